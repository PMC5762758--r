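#' Plot a 96-context mutation spectrum
#'
#' Standard signature-style barplot: one bar per trinucleotide context,
#' faceted by the six substitution types.
#'
#' @param catalog Catalog tibble from [build_catalog()].
#' @param samples Samples to plot (default: all).
#' @return A ggplot object.
#' @export
plot_catalog <- function(catalog, samples = NULL) {
  long <- tidyr::pivot_longer(catalog, -"context", names_to = "sample",
                              values_to = "count")
  if (!is.null(samples)) long <- dplyr::filter(long, .data$sample %in% samples)
  long$substitution <- substr(long$context, 3, 5)
  long$flank <- paste0(substr(long$context, 1, 1), ".",
                       substr(long$context, 7, 7))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$flank, y = .data$count,
                                     fill = .data$substitution)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(sample ~ substitution, scales = "free_y") +
    ggplot2::labs(x = "flanking bases", y = "mutation count") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 5))
}

#' Plot fitted signature exposures with confidence intervals
#'
#' @param object An `"exposure_fit"`.
#' @param relative Plot relative exposures instead of counts
#'   (CIs are drawn only on the absolute scale).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exposure_fit <- function(object, relative = FALSE, ...) {
  df <- dplyr::filter(object$exposures, .data$retained)
  if (relative) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample,
                                          y = .data$rel_exposure,
                                          fill = .data$signature)) +
      ggplot2::geom_col() +
      ggplot2::labs(y = "relative exposure")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$signature,
                                          y = .data$exposure)) +
      ggplot2::geom_col(fill = "grey70") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi),
                             width = 0.2, na.rm = TRUE) +
      ggplot2::facet_wrap(~sample) +
      ggplot2::labs(y = "exposure (mutations)")
  }
  p + ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a segmented copy-number profile
#'
#' Draws segments as horizontal bars at their copy-number state (or log2
#' ratio), one panel per sample; oscillating two-state patterns are
#' immediately visible.
#'
#' @param seg Segment table with `state` or `log2`.
#' @param y Which value to plot, `"state"` (default) or `"log2"`.
#' @return A ggplot object.
#' @export
plot_segment_profile <- function(seg, y = c("state", "log2")) {
  y <- match.arg(y)
  seg <- validate_segments(seg)
  if (!y %in% names(seg)) abort(paste0("`seg` has no '", y, "' column"))
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start / 1e6,
                                       xend = .data$end / 1e6,
                                       y = .data[[y]],
                                       yend = .data[[y]]),
                          linewidth = 1.2, colour = "firebrick") +
    ggplot2::facet_grid(sample ~ chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = y) +
    ggplot2::theme_minimal()
}

#' Plot C-circle classification
#'
#' Scatter of polymerase signal against the classification floor
#' (the larger of twofold no-polymerase and threefold background), with
#' the decision boundary as the identity line.
#'
#' @param classified Output of [classify_alt()].
#' @return A ggplot object.
#' @export
plot_alt_classification <- function(classified) {
  stopifnot("status" %in% names(classified))
  df <- dplyr::mutate(
    as_tibble(classified),
    floor_intensity = pmax(2 * .data$intensity_nopol, 3 * .data$background)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$floor_intensity,
                                   y = .data$intensity_pol,
                                   colour = .data$status)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "classification floor (max of 2 x -pol, 3 x background)",
                  y = "+pol intensity") +
    ggplot2::theme_minimal()
}
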