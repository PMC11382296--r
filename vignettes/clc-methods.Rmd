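---
title: "Detecting cardiac-locomotor coupling in wearable data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cardiac-locomotor coupling in wearable data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clcoupling)
```

## The problem

Cardiac-locomotor coupling (CLC) is 1:1 frequency locking between the heart
and the stepping rhythm: the heart beats once per stride. Sustained coupling
— especially with steps timed to diastole — has been proposed to aid muscle
perfusion, which makes its *spontaneous* prevalence during ordinary daily
life an interesting physiological quantity. Consumer wrist devices record
step counts every minute and heart rate every few seconds over months, so
free-living prevalence can be estimated from them, at minute resolution,
despite their noise.

`clcoupling` implements that analysis as a tested pipeline:

1. **Ingest**: average heart rate (HR) to calendar minutes, synchronise with
   the per-minute step rate (SR) by timestamp, and keep only active minutes
   (SR ≥ 60 steps/min, the conventional slow-walking cut).
2. **Classification**: per minute, the coupling ratio $R = \mathrm{SR}/\mathrm{HR}$
   and its deviation $|R-1|$; CLC when the deviation is ≤ 1%, weak CLC in
   (1%, 10%], no CLC otherwise. Cadence bands 60/100/130 steps/min proxy
   light/moderate/vigorous intensity.
3. **Bouts**: maximal runs of active minutes with gaps < 60 min; inclusive
   duration; a bout-level coupling label.
4. **Null model**: the distribution of $R_\mathrm{sim} = \mathrm{SR}_j/\mathrm{HR}_i$
   over all $N\times N$ random pairings of a subject's recorded values —
   what coincidence alone would produce given the subject's marginal HR and
   SR distributions.
5. **Statistics**: Wilcoxon signed-rank with effect size $r = |Z|/\sqrt{N}$,
   Kruskal–Wallis with $\eta^2 = H/(N-1)$, Friedman, a chi-squared normality
   check, Pearson correlation, Kolmogorov–Smirnov distribution comparison.
6. **Synthetic cohorts**: a seeded generator with ground-truth entrainment
   labels, so every stage can be validated without access to a real cohort.

## Minute alignment choices

Samples are assigned to the minute their timestamp floor-truncates to,
matching how the device itself aggregates steps. A minute mean is emitted
only when at least `min_samples = 6` of the nominal 12 five-second samples
are present; source recordings do not state a completeness rule, so it is a
package default and configurable. The activity filter keeps SR **≥** 60
(the boundary minute is active); the source convention "below 60 excluded"
does not state the boundary, so this reading is explicit and configurable.
Timestamps are treated as local wall clock without timezone conversion —
the analysis only uses time-of-day and gaps. HR minutes without a step
record are dropped by the inner join rather than treated as SR = 0; the
alternative would only add sub-threshold minutes that the filter removes.

Band edges are applied with an absolute guard of $10^{-12}$ so that decimal
thresholds behave as written (in binary floating point $|99/100 - 1|$
evaluates one ulp above 0.01).

## The random-pairing null

Because HR and SR are physiologically related, some minutes satisfy
$|R-1| \le 0.01$ by coincidence. The null model quantifies that: pair every
recorded HR value with every recorded SR value of the same subject and ask
how often the ratio lands in the coupling bands.

The default implementation is **exact**, not Monte Carlo. For bin
$[a, b)$ the pairing mass is $\frac{1}{N^2}\sum_h \#\{s : a h \le s < b h\}$,
computed by sorting the SR values once and binary-searching the scaled bin
edges — identical (to $10^{-12}$; tested against brute-force $N^2$
enumeration) but $O(B\,N\log N)$. Quantiles are found by bisection on the
exact pairing CDF; skewness uses the exact moment identity
$E[R^k] = E[\mathrm{SR}^k]\,E[\mathrm{HR}^{-k}]$ under independent pairing
(population third standardized moment). A seeded Monte Carlo variant
(`null_sampled()`) is retained for fidelity with common practice and
converges to the exact result; sample summaries there use the adjusted
Fisher–Pearson skewness, since draws are a sample rather than a
distribution. Histograms use 1%-wide bins on $R \in [0.3, 3.0)$ — the range
reachable by 60–200 steps/min against plausible heart rates — with
underflow/overflow bins so probabilities always sum to one.

The observed-vs-null comparison uses the value-sample Kolmogorov–Smirnov
statistic: two-sample against the draws when the null is sampled, and
against the exact pairing CDF (with correct handling of its jumps, and the
asymptotic Kolmogorov p-value) when exact. `delta_p` is the observed minus
null probability of the combined CLC + weak band — the "how much more
coupling than chance" headline.

Nulls are built per subject; cohort statements aggregate per-subject
values by the median and compare paired quantities with the Wilcoxon
signed-rank test, matching the median (IQR) reporting convention of this
literature.

## Effect sizes and test conventions

The signed-rank Z uses the normal approximation with continuity correction
and average ranks for ties (zero differences dropped), so a standardized Z
always exists for $r = |Z|/\sqrt{N}$; $N$ is the number of pairs supplied.
For Kruskal–Wallis, $\eta^2 = H/(N-1)$ is the default; an $H/N$ variant is
available behind `eta_denominator = "n"` because both normalisations appear
in applied work. The chi-squared normality check bins into equal-probability
classes under the fitted normal ($df = k - 3$) and flags itself when
expected counts are too small. No multiple-testing correction is applied
anywhere; reported p-values are raw, by design, and documented as such.

## What the synthetic generator emulates

The generator simulates each subject minute-by-minute:

* **Schedule.** Bouts are scheduled 06:00–23:00 (Poisson count per day,
  default 3/day; normal durations 60 ± 30 min truncated to [10, 180]) with
  at least 90 minutes between bouts, so 60-minute-gap segmentation recovers
  the schedule. Sleep (23:00–06:00) has SR = 0, guaranteeing multi-hour
  gaps. Resting minutes draw small Poisson step counts below the filter.
* **Step rate.** Within a bout the true SR wanders around a per-bout
  cadence drawn uniformly from 60–180 steps/min (AR(1) wander plus white
  minute noise), reflecting free-living cadence variability.
* **Heart rate.** True HR relaxes with a ~2-minute time constant towards a
  target: resting HR (drawn per subject from 47–70 beats/min) plus a
  per-bout elevation drawn uniformly from 20–110 beats/min, with its own
  slow wander. Crucially, the elevation is drawn **independently of the
  bout cadence** (see below).
* **Entrainment.** A fraction `couple_fraction` of bout minutes has true
  SR set equal to the noiseless minute-mean HR, before sensor noise.
  Minute-level probabilities are proportional to bout duration (water-filled
  so the expected overall fraction is exact, and `couple_fraction = 1`
  entrains every bout minute); sustained activities are where locking
  emerges, and this makes coupled bouts longer on average. Entrainment is
  applied at minute level because the pipeline's resolution is one minute;
  within-beat phase is out of scope.
* **Sensor model.** HR is emitted as integer 5-second samples with
  multiplicative Gaussian noise calibrated so the per-sample mean absolute
  percentage error equals `hr_noise_mape` (default 11%, the figure reported
  for this class of wrist PPG sensor). SR is emitted as per-minute integers
  after a proportional bias (default −3%, the reported median step
  undercount) and additive jitter (default SD 2 steps/min).

One root seed; subject $i$ uses `seed + i`, so cohorts are reproducible
file-for-file and subjects individually regenerable.

### Why HR is independent of cadence in the generator

Real HR rises with cadence. But a generator whose HR depends on SR builds
coupling into *every* minute, making the random-pairing null miscalibrated
under the generator's own "no entrainment" setting — there would be no
configuration in which observed and null distributions agree, and
`couple_fraction` would no longer be the ground truth for "how much
entrainment is present". Drawing the bout HR elevation independently of
cadence makes HR ⟂ SR exact when `couple_fraction = 0`, so null-model
calibration can be tested cleanly. The price is realism: default synthetic
cohorts have near-zero HR–SR Pearson correlation, whereas real cohorts show
0.3–0.8. Passing calibration tests therefore shows the null machinery is
correct under its own hypothesis — not that real free-living data satisfy
that hypothesis.

### What passing tests do and do not show

Three structural facts about this setting, verified quantitatively by the
test suite and worth stating plainly:

* **Chance coupling is not negligible.** With overlapping HR and SR
  supports, roughly 2% of independent active minutes land in the 1% band —
  the null rate. Observed CLC occurrence is therefore approximately
  `couple_fraction + (1 − couple_fraction) ×` null rate even with perfect
  sensors; recovery of the injected fraction must subtract the null rate,
  which is exactly what the observed-vs-null design is for.
* **A −3% step-rate bias dominates a 1% band.** An entrained minute's
  measured deviation centres near 3%, so only ~10–15% of truly entrained
  minutes are *measured* as CLC under default noise; most appear as weak
  CLC. Absolute CLC occurrence consequently under-recovers the injected
  entrainment at realistic noise, while the distributional excess over the
  null remains detectable. Occurrence alone conflates chance, sensor error
  and coupling — the null comparison is the meaningful readout.
* **Minutes are not independent.** Minutes within a bout share cadence and
  HR level, so per-subject empirical band probabilities fluctuate around
  the null with an effective sample size closer to the number of bouts than
  the number of minutes, and the iid-based KS test is anticonservative on
  bout-structured series even without any entrainment. Cross-subject paired
  tests (each subject contributing one number) remain valid; per-subject
  KS significance should be read with this in mind. Surrogate methods that
  preserve autocorrelation would address this and are deliberately out of
  scope.

## Numerical and degenerate-input choices

* Exact null quantiles: 90 bisection steps on the discrete CDF (resolution
  far below data noise); ties in the KS statistic handled via left and
  right CDF limits.
* All-zero paired differences: flagged result with undefined Z, never a
  silent zero. Friedman with identical conditions in every block: statistic
  0 by convention (the tie-corrected form is 0/0).
* Empty subjects (no post-filter minutes) yield flagged empty reports and
  are excluded from cohort medians with a warning.
* Bout labels: the strongest coupling class covering ≥ 20% of a bout's
  minutes, else the modal class (ties to the stronger class). The 20% rule
  is a package choice — source conventions do not state how a bout acquires
  a coupling label — and is configurable.
* Duplicate step minutes keep the first record; non-integer step values are
  rejected, not rounded; HR samples outside (20, 250) beats/min are
  rejected and counted.

## Problem sizes

Default validation cohorts are 16 subjects × 14 days (≈ 1,600–2,600 active
minutes per subject), which keeps the full suite and the reproduction
script fast while leaving every statistic well inside its asymptotic
regime; calibration checks that need tighter binomial tolerances use longer
single-subject runs (up to 150 days, the duration of the motivating
five-month protocol). The exact null is $O(B\,N\log N)$ and handles
five-month subjects (≈ 25,000 active minutes) in under a second.

## Interface notes

The package is a set of pipe-friendly functions over tibbles; there is no
separate command-line binary — `scripts/acceptance.R` shows the end-to-end
invocation, and every threshold (activity filter, bands, intensity cuts,
gap, grouping cutoff, null method, age split) is an argument of
`cohort_config()` / `analysis_config()`.

## Known limitations

* Only 1:1 locking is considered; 2:1 or 1:2 ratios would appear as no-CLC.
* Phase within the cardiac cycle (diastolic vs systolic stepping) is not
  observable at minute resolution and is out of scope.
* Cadence is an intensity proxy; no MET/oxygen-consumption computation.
* The null model treats minutes as exchangeable; see the autocorrelation
  caveat above.
* The generator is a validation scaffold, not a physiological model: no
  HRV, no circadian HR rhythm, no accelerometry, and deliberately no
  HR–cadence dependence outside entrainment.
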