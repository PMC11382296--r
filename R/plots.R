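# Simple ggplot2 views of the result objects.

#' Plot coupling-class occurrence
#'
#' Bar chart of occurrence percentages, optionally faceted by intensity
#' class when the summary is stratified.
#'
#' @param occ tibble from [occurrence()].
#' @return a ggplot object.
#' @export
plot_occurrence <- function(occ) {
  p <- ggplot2::ggplot(
    occ,
    ggplot2::aes(x = .data$coupling_class, y = .data$percentage)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "occurrence (% of active minutes)"
    ) +
    ggplot2::theme_minimal()
  if ("intensity_class" %in% names(occ)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$intensity_class))
  }
  p
}

#' @rdname plot_null_comparison
#' @param object a `clc_distribution`.
#' @param ... ignored.
#' @method autoplot clc_distribution
#' @export
autoplot.clc_distribution <- function(object, ...) {
  h <- object$histogram
  h <- h[is.finite(h$bin_left) & is.finite(h$bin_right), ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_left, y = .data$probability)) +
    ggplot2::geom_col(width = h$bin_right[1] - h$bin_left[1], just = 0) +
    ggplot2::labs(
      x = "coupling ratio R", y = "probability",
      title = sprintf("%s R distribution", object$method)
    ) +
    ggplot2::theme_minimal()
}

#' Overlay observed and null coupling-ratio histograms
#'
#' @param observed,null `clc_distribution` objects on the same bin grid.
#' @return a ggplot object.
#' @export
plot_null_comparison <- function(observed, null) {
  grab <- function(d, label) {
    h <- d$histogram
    h <- h[is.finite(h$bin_left) & is.finite(h$bin_right), ]
    h$distribution <- label
    h
  }
  dat <- dplyr::bind_rows(grab(observed, "observed"), grab(null, "null"))
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = .data$bin_left, y = .data$probability,
      colour = .data$distribution
    )
  ) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "coupling ratio R", y = "probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
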