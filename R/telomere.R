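#' Classify ALT status from C-circle dot-blot intensities
#'
#' C-circles (partially single-stranded extrachromosomal telomeric-repeat
#' circles) are a specific marker of alternative lengthening of telomeres
#' (ALT). They are amplified with Phi29 polymerase and detected as
#' chemiluminescent dot-blot signal. A sample is ALT-positive when the
#' complete reaction's signal is at least twofold the no-polymerase
#' control signal and at least threefold the membrane background
#' (both thresholds inclusive). Samples with any missing intensity are
#' reported as not determined.
#'
#' @param ccircle Data frame with columns `sample`, `intensity_pol`
#'   (with polymerase), `intensity_nopol` (without polymerase) and
#'   `background`. All intensities must be non-negative.
#' @param fold_nopol,fold_background Fold-change thresholds (defaults 2
#'   and 3).
#' @return The input with a `status` column in
#'   `{"positive", "negative", "not_determined"}`.
#' @export
#' @examples
#' classify_alt(tibble::tibble(sample = "T1", intensity_pol = 6,
#'                             intensity_nopol = 2, background = 1))
classify_alt <- function(ccircle, fold_nopol = 2, fold_background = 3) {
  ccircle <- as_tibble(ccircle)
  cols <- c("intensity_pol", "intensity_nopol", "background")
  stopifnot(all(c("sample", cols) %in% names(ccircle)))
  vals <- as.matrix(ccircle[cols])
  if (any(vals < 0, na.rm = TRUE)) abort("intensities must be non-negative")
  nd <- apply(is.na(vals), 1, any)
  pos <- ccircle$intensity_pol >= fold_nopol * ccircle$intensity_nopol &
    ccircle$intensity_pol >= fold_background * ccircle$background
  ccircle$status <- dplyr::case_when(
    nd ~ "not_determined",
    pos ~ "positive",
    TRUE ~ "negative"
  )
  ccircle
}

#' Telomere-content T/S ratios from quantitative PCR
#'
#' Telomere repeat qPCR signal (T) is normalized to a single-copy gene
#' (36B4; S), giving a T/S ratio per sample, and the tumor ratio is
#' divided by the matched control ratio. The log2 of that quotient is the
#' relative increase or decrease in telomere content of the tumor.
#'
#' @param qpcr Data frame with columns `sample`, `tumor_t`, `tumor_s`,
#'   `control_t`, `control_s`. S signals must be strictly positive.
#' @return The input with columns `tumor_ts`, `control_ts` and
#'   `log2_ratio` added.
#' @export
ts_ratio <- function(qpcr) {
  qpcr <- as_tibble(qpcr)
  cols <- c("tumor_t", "tumor_s", "control_t", "control_s")
  stopifnot(all(c("sample", cols) %in% names(qpcr)))
  if (any(qpcr$tumor_s <= 0) || any(qpcr$control_s <= 0)) {
    abort("single-copy-gene (S) signals must be strictly positive")
  }
  qpcr$tumor_ts <- qpcr$tumor_t / qpcr$tumor_s
  qpcr$control_ts <- qpcr$control_t / qpcr$control_s
  qpcr$log2_ratio <- log2(qpcr$tumor_ts / qpcr$control_ts)
  qpcr
}

#' Association between ALT status and a binary sample feature
#'
#' Tests whether a per-sample feature (e.g. deletion of a telomere-
#' maintenance gene) is associated with ALT positivity, by a two-sided
#' Fisher exact test on the 2x2 table. Samples with status
#' `"not_determined"` are excluded first.
#'
#' @param data Data frame with a `status` column (from [classify_alt()],
#'   or logical/`"positive"`/`"negative"`) and a logical `feature` column.
#' @param feature Name of the feature column (default `"feature"`).
#' @return One-row tibble: the four table cells, `odds_ratio`, `p_value`
#'   and `n_excluded`.
#' @export
alt_association <- function(data, feature = "feature") {
  data <- as_tibble(data)
  stopifnot("status" %in% names(data), feature %in% names(data))
  status <- data$status
  if (is.logical(status)) status <- ifelse(status, "positive", "negative")
  keep <- status %in% c("positive", "negative") & !is.na(data[[feature]])
  n_excluded <- sum(!keep)
  status <- status[keep]
  feat <- as.logical(data[[feature]][keep])
  if (length(status) == 0) abort("no classifiable samples left after exclusion")
  tab <- table(factor(status == "positive", levels = c(TRUE, FALSE)),
               factor(feat, levels = c(TRUE, FALSE)))
  ft <- fisher.test(tab, alternative = "two.sided")
  tibble(
    alt_with_feature = tab[1, 1], alt_without_feature = tab[1, 2],
    nonalt_with_feature = tab[2, 1], nonalt_without_feature = tab[2, 2],
    odds_ratio = unname(ft$estimate), p_value = ft$p.value,
    n_excluded = n_excluded
  )
}
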