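#' Validate and order a segment profile
#'
#' @param seg Data frame with columns `sample`, `chrom`, `start`, `end`
#'   (1-based inclusive) and at least one of `log2`, `state`.
#' @return The segments as a tibble, sorted by sample, chromosome, start.
#' @keywords internal
validate_segments <- function(seg) {
  seg <- as_tibble(seg)
  required <- c("sample", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(seg))
  if (length(missing_cols) > 0) {
    abort(paste0("segment table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!any(c("log2", "state") %in% names(seg))) {
    abort("segment table needs a `log2` and/or `state` column")
  }
  if (any(seg$end < seg$start)) abort("segment with end < start")
  seg <- dplyr::arrange(seg, .data$sample, .data$chrom, .data$start)
  overlap <- seg |>
    dplyr::group_by(.data$sample, .data$chrom) |>
    dplyr::summarise(
      bad = any(.data$start[-1] <= .data$end[-dplyr::n()]) && dplyr::n() > 1,
      .groups = "drop"
    )
  if (any(overlap$bad)) {
    abort("overlapping segments within a chromosome")
  }
  seg
}

#' Correct segment log2 ratios for whole-chromosome gains and losses
#'
#' Read-depth log2 ratios computed against a pooled reference are biased
#' on chromosomes that are gained or lost as a whole. The correction
#' shifts every segment's log2 ratio by
#' `log2(tumor_fraction / normal_fraction)`, where the fractions are the
#' proportions of total reads mapping to that chromosome in the tumor and
#' the matched normal. Segment boundaries are unchanged.
#'
#' @param seg Segment table (see [validate_segments()]) with a `log2`
#'   column.
#' @param fractions Tibble with columns `chrom`, `tumor_fraction`,
#'   `normal_fraction` (and optionally `sample` for per-sample
#'   correction). Fractions must be strictly positive.
#' @return The segment table with corrected `log2` values.
#' @export
correct_log2 <- function(seg, fractions) {
  seg <- validate_segments(seg)
  if (!"log2" %in% names(seg)) abort("`seg` has no log2 column to correct")
  fractions <- as_tibble(fractions)
  stopifnot(all(c("chrom", "tumor_fraction", "normal_fraction") %in%
                  names(fractions)))
  if (any(fractions$tumor_fraction <= 0) ||
      any(fractions$normal_fraction <= 0)) {
    abort("read fractions must be strictly positive")
  }
  by <- if ("sample" %in% names(fractions)) c("sample", "chrom") else "chrom"
  out <- dplyr::left_join(seg, fractions, by = by)
  if (any(is.na(out$tumor_fraction))) {
    abort("some segments have no matching read-fraction entry")
  }
  out$log2 <- out$log2 + log2(out$tumor_fraction / out$normal_fraction)
  dplyr::select(out, -"tumor_fraction", -"normal_fraction")
}

#' Discretize log2 ratios into integer copy-number states
#'
#' Maps each segment's log2 ratio to `round(baseline * 2^log2)`, floored
#' at 0. Segments that already carry a (non-missing) integer `state` pass
#' through untouched, so externally derived states are respected.
#'
#' @param seg Segment table with a `log2` column.
#' @param baseline Copy number corresponding to log2 = 0 (default 2,
#'   diploid).
#' @return The segment table with a `state` column.
#' @export
discretize_states <- function(seg, baseline = 2) {
  seg <- validate_segments(seg)
  if (!"state" %in% names(seg)) seg$state <- NA_real_
  needs <- is.na(seg$state)
  if (any(needs) && !"log2" %in% names(seg)) {
    abort("segments without a state need a log2 column")
  }
  if (any(needs)) {
    seg$state[needs] <- pmax(round(baseline * 2^seg$log2[needs]), 0)
  }
  seg
}

## enumerate maximal two-state oscillating runs in a state sequence;
## returns a list of integer index ranges (start, end) of runs with >= 1 switch
oscillating_runs <- function(states) {
  n <- length(states)
  runs <- list()
  if (n < 2) return(runs)
  a <- 1
  j <- 2
  while (j <= n) {
    ok <- states[j] != states[j - 1] &&
      (j - a < 2 || states[j] == states[j - 2])
    if (ok) {
      j <- j + 1
    } else {
      if (j - 1 > a) runs[[length(runs) + 1]] <- c(a, j - 1)
      ## a new alternation can start at the previous segment when the
      ## break was a third state, or at the current one when states repeat
      a <- if (states[j] != states[j - 1]) j - 1 else j
      j <- max(j, a + 1)
      if (a == j) j <- j + 1
    }
  }
  if (n > a) runs[[length(runs) + 1]] <- c(a, n)
  runs
}

#' Count alternating copy-number state switches per chromosome
#'
#' A switch is a change of state between adjacent segments that takes part
#' in an oscillation between exactly two states (A,B,A,B,...). For each
#' chromosome the maximal oscillating run with the most switches is
#' selected (ties broken by the smaller span, i.e. the denser run) and
#' its switch count and affected span are reported. The span is the
#' distance in Mb between the first and the last switch breakpoint of the
#' run, each breakpoint being the midpoint between the flanking segments.
#' With `policy = "any-change"` every adjacent state change counts as a
#' switch instead, and the span runs from the first to the last change.
#'
#' @param seg Segment table with a `state` column (see
#'   [discretize_states()]).
#' @param policy `"two-state"` (default) or `"any-change"`.
#' @return Tibble with one row per `sample` x `chrom`: `n_switches`,
#'   `span_mb`. Flat chromosomes report `(0, 0)`.
#' @export
count_switches <- function(seg, policy = c("two-state", "any-change")) {
  policy <- match.arg(policy)
  seg <- validate_segments(seg)
  if (!"state" %in% names(seg)) abort("`seg` has no state column; run discretize_states() first")
  if (any(is.na(seg$state))) abort("missing states in `seg`")
  seg |>
    dplyr::group_by(.data$sample, .data$chrom) |>
    dplyr::group_modify(function(d, key) {
      res <- switch_run_stats(d$state, d$start, d$end, policy)
      tibble(n_switches = res$n_switches, span_mb = res$span_mb)
    }) |>
    dplyr::ungroup()
}

switch_run_stats <- function(states, start, end, policy) {
  n <- length(states)
  ## breakpoint between segments i and i+1
  breakpoint <- function(i) (end[i] + start[i + 1]) / 2
  if (n < 2) return(list(n_switches = 0, span_mb = 0))
  if (policy == "any-change") {
    ch <- which(states[-1] != states[-n])
    if (length(ch) == 0) return(list(n_switches = 0, span_mb = 0))
    span <- if (length(ch) < 2) 0 else
      (breakpoint(ch[length(ch)]) - breakpoint(ch[1])) / 1e6
    return(list(n_switches = length(ch), span_mb = span))
  }
  runs <- oscillating_runs(states)
  if (length(runs) == 0) return(list(n_switches = 0, span_mb = 0))
  stats <- purrr::map(runs, function(r) {
    sw <- r[2] - r[1]               # adjacent changes inside the run
    span <- if (sw < 2) 0 else (breakpoint(r[2] - 1) - breakpoint(r[1])) / 1e6
    c(sw = sw, span = span)
  })
  sw <- purrr::map_dbl(stats, "sw")
  span <- purrr::map_dbl(stats, "span")
  best <- which(sw == max(sw))
  best <- best[which.min(span[best])]
  list(n_switches = sw[best], span_mb = span[best])
}

#' Call chromothripsis per chromosome by switch density
#'
#' Chromothripsis produces copy-number profiles that oscillate between two
#' states across a confined region. The caller counts alternating state
#' switches ([count_switches()]) and computes the switch density
#' `ratio = n_switches / span_mb`. A chromosome is called positive when it
#' has at least `min_switches` alternating switches and the density is at
#' least `min_ratio` (default 0.2 switches/Mb, so 10 switches within
#' 50 Mb, or the minimum 6 switches within 30 Mb, are positive). The
#' density cut-off guards against calling sparse scattered switches on
#' long chromosomes, where many switches can arise by chance.
#'
#' @param seg Segment table with `state` (or `log2`, which is discretized
#'   with the default diploid baseline first).
#' @param min_switches Minimum alternating switch count (default 6).
#' @param min_ratio Minimum switches/Mb, inclusive (default 0.2).
#' @param policy Switch-counting policy, see [count_switches()].
#' @return Tibble with one row per `sample` x `chrom`: `n_switches`,
#'   `span_mb`, `ratio` and `positive`. `ratio` is 0 when fewer than two
#'   switches exist (no span) and infinite for a zero-length span.
#' @export
call_chromothripsis <- function(seg, min_switches = 6, min_ratio = 0.2,
                                policy = c("two-state", "any-change")) {
  policy <- match.arg(policy)
  seg <- discretize_states(seg)
  calls <- count_switches(seg, policy = policy)
  calls$ratio <- ifelse(calls$n_switches < 2, 0,
                        ifelse(calls$span_mb > 0,
                               calls$n_switches / calls$span_mb, Inf))
  calls$positive <- calls$n_switches >= min_switches &
    calls$ratio >= min_ratio
  calls
}

#' Per-sample chromothripsis summary
#'
#' @param calls Per-chromosome calls from [call_chromothripsis()].
#' @return Tibble with one row per sample: `n_affected_chromosomes`,
#'   `chromothripsis` (any positive chromosome).
#' @export
summarize_chromothripsis <- function(calls) {
  calls |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_affected_chromosomes = sum(.data$positive),
                     chromothripsis = any(.data$positive),
                     .groups = "drop")
}
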