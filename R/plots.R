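#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_point geom_segment
#'   labs scale_y_continuous facet_wrap theme_minimal
NULL

#' Plot a repeat landscape
#'
#' Stacked histogram of annotated bases by divergence bin, coloured by
#' family.
#'
#' @param object a `te_landscape` from [divergence_landscape()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.te_landscape <- function(object, ...) {
  ggplot(object, aes(x = .data$bin_lo, y = .data$bases,
                     fill = .data$family)) +
    geom_col(position = "stack", width = object$bin_hi[1] - object$bin_lo[1]) +
    labs(x = "Divergence from consensus (%)", y = "Annotated bases",
         fill = "Family") +
    theme_minimal()
}

#' @rdname autoplot.te_landscape
#' @param x a `te_landscape`.
#' @export
plot_landscape <- function(x, ...) autoplot(x, ...)

#' Plot detection coverage against reference identity
#'
#' @param object a `te_coverage` from [coverage_by_identity()], or a
#'   row-bound tibble of several with a `tool` column for comparison.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.te_coverage <- function(object, ...) {
  mid <- (object$bin_lo + object$bin_hi) / 2
  p <- ggplot(dplyr::mutate(object, mid = mid),
              aes(x = .data$mid, y = .data$coverage))
  if ("tool" %in% names(object)) {
    p <- p + geom_line(aes(colour = .data$tool)) +
      geom_point(aes(colour = .data$tool))
  } else {
    p <- p + geom_line() + geom_point()
  }
  p + scale_y_continuous(limits = c(0, 1)) +
    labs(x = "Reference identity (%)", y = "Fraction of TE bases detected") +
    theme_minimal()
}

#' @rdname autoplot.te_coverage
#' @param x a `te_coverage`.
#' @export
plot_coverage_by_identity <- function(x, ...) autoplot(x, ...)

#' Plot annotation tracks against the reference
#'
#' One horizontal track per prediction set, with segments coloured by
#' their base-level class (TP / FP / FN) within the exported region.
#'
#' @param object a `te_tracks` from [track_table()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.te_tracks <- function(object, ...) {
  ggplot(object, aes(y = .data$track)) +
    geom_segment(aes(x = .data$start, xend = .data$end,
                     yend = .data$track, colour = .data$class),
                 linewidth = 4) +
    labs(x = "Position (bp)", y = NULL, colour = "Class") +
    theme_minimal()
}

#' @rdname autoplot.te_tracks
#' @param x a `te_tracks`.
#' @export
plot_tracks <- function(x, ...) autoplot(x, ...)
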