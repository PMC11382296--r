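# clcoupling

Cardiac-locomotor coupling (CLC) analysis for wearable heart-rate and step
data.

CLC is 1:1 frequency locking between the cardiac and locomotor rhythms: the
heart beats once per stride. Because stepping timed to diastole can aid
muscle perfusion, how often people couple *spontaneously* in daily life is a
physiologically interesting quantity — and one that months-long smartwatch
recordings (per-minute step counts, 5-second heart-rate samples) can
estimate. `clcoupling` is for researchers who want that estimate with its
chance level made explicit, plus the machinery to validate every step of the
computation on synthetic cohorts with known ground truth.

## The method

For every aligned active minute (step rate SR ≥ 60 steps/min after
timestamp synchronisation and per-minute HR averaging) the pipeline
computes the coupling ratio

> R = SR / HR

and classifies by the deviation |R − 1|: **CLC** (≤ 1%), **weak CLC**
(1–10%], **no CLC** (> 10%). Minutes are stratified by cadence intensity
(light/moderate/vigorous at 60/100/130 steps/min) and segmented into
activity bouts (gaps < 60 min). Because HR and SR can coincide by chance,
each subject's observed R distribution is compared against the exact
**random-pairing null**: the distribution of R_sim = SR_j / HR_i over all
N × N pairings of that subject's recorded values, computed without sampling
by sorted counting (a seeded Monte Carlo variant is also provided). The
headline readouts are `delta_p` — the observed minus null probability of
the combined CLC + weak band — and a Kolmogorov–Smirnov comparison.
Cohort summaries use medians (IQR) across subjects with Wilcoxon
signed-rank contrasts (effect size r = |Z|/√N) and Kruskal–Wallis
(η² = H/(N−1)).

A seeded synthetic-cohort generator emulates the recording protocol
(activity bouts 06:00–23:00, sleep gaps, 60–180 steps/min cadences,
first-order HR response, −3% step undercount, 11% HR sample MAPE) and
injects a known fraction of truly entrained minutes, so parameter recovery
and null calibration are testable end to end. See the methods vignette
(`vignettes/clc-methods.Rmd`) for the model, the design decisions and what
the synthetic validation does and does not establish.

## Worked example

```r
library(clcoupling)

cfg <- cohort_config(n_subjects = 2, days = 14, seed = 7, couple_fraction = 0.05)
s   <- generate_subject(cfg, 1)
s
#> <clc_subject_streams> S01: 241920 HR samples, 20160 step minutes, 29 bouts, 97 entrained minutes

rep <- run_subject(s$heart_rate, s$steps, subject_id = "S01")
rep$tables$occurrence
#> # A tibble: 3 x 3
#>   coupling_class     n percentage
#>   <fct>          <int>      <dbl>
#> 1 CLC               50       2.62
#> 2 weak_CLC         307      16.1
#> 3 no_CLC          1555      81.3

tidy(rep$tables$null)
#> # A tibble: 1 x 6
#>   method  p_clc p_weak_or_clc median   iqr skewness
#> 1 exact  0.0184         0.179  0.934 0.584    0.808

rep$tables$comparison[, c("ks_statistic", "ks_p", "delta_p")]
#> # A tibble: 1 x 3
#>   ks_statistic   ks_p delta_p
#> 1       0.0311 0.0482 0.00722
```

Reading this: of 1,912 active minutes, 2.62% were within 1% of 1:1 locking —
but random pairing of this subject's own HR and SR values already puts 1.84%
there (`p_clc`), so most of the raw occurrence is coincidence; the excess of
the combined CLC + weak band over chance is `delta_p` = 0.7 percentage
points. `plot_null_comparison(rep$tables$observed, rep$tables$null)` overlays
the two histograms; `run_cohort()` aggregates subjects, runs the paired
contrasts and the moderate-vs-vigorous grouping (D statistic at ±1.5 pp).

With the original wrist-worn recordings (PMData, OSF `vx4bk`, not shipped
here) the same pipeline applies unchanged: point `run_cohort()` at a
directory of per-subject files in either supported dialect (`csv` or
`fitbit-json`).

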