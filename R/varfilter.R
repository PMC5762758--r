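#' SNV filter rule identifiers, in application order
#'
#' @return Character vector of the seven rule ids.
#' @export
snv_filter_rules <- function() {
  c("min_variant_reads", "min_vaf", "strand_error_profile",
    "control_coverage", "control_variant_fraction",
    "mappability_blacklist", "repeat_overlap")
}

.blacklist_classes <- c("low-mappability", "blacklist")
.repeat_classes <- c("tandem-repeat", "simple-repeat", "low-complexity",
                     "satellite", "segmental-duplication")

#' Heuristic tumor/normal filtering of candidate SNVs
#'
#' Applies the high-confidence somatic SNV filter chain, in fixed order:
#' (1) at least `min_variant_reads` tumor variant reads; (2) variant
#' allele frequency at least `min_vaf`; (3) calls supported by reads from
#' only one strand are discarded when a sequencing error-profile context
#' is present; (4) control coverage at least `min_control_coverage`;
#' (5) fewer than `max_control_fraction` of control bases may support the
#' tumor variant; (6) no overlap with low-mappability or blacklist
#' regions; (7) no simultaneous overlap with two or more repeat classes
#' (tandem repeats, simple repeats, low complexity, satellites,
#' segmental duplications). Records with missing control fields get a
#' `NA` verdict (not determined).
#'
#' @param snvs Data frame with columns `variant_reads`, `total_reads`,
#'   `forward_variant_reads`, `reverse_variant_reads`,
#'   `control_coverage`, `control_variant_bases`, and optionally
#'   `error_profile` (logical; default `FALSE`, which disables rule 3)
#'   and `regions` (list column of region-class names from
#'   [annotate_regions()]; default none).
#' @param min_variant_reads,min_vaf,min_control_coverage,
#'   max_control_fraction Thresholds; defaults 5, 0.05 (inclusive), 10,
#'   1/30 (exclusive).
#' @return The input with `failed_rules` (list column of rule ids, in
#'   order) and `pass` (logical; `NA` when control fields are missing).
#' @export
filter_snv <- function(snvs, min_variant_reads = 5, min_vaf = 0.05,
                       min_control_coverage = 10,
                       max_control_fraction = 1 / 30) {
  snvs <- as_tibble(snvs)
  required <- c("variant_reads", "total_reads", "forward_variant_reads",
                "reverse_variant_reads", "control_coverage",
                "control_variant_bases")
  missing_cols <- setdiff(required, names(snvs))
  if (length(missing_cols) > 0) {
    abort(paste0("`snvs` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  counts <- snvs[c("variant_reads", "total_reads", "forward_variant_reads",
                   "reverse_variant_reads")]
  if (any(as.matrix(counts) < 0, na.rm = TRUE)) {
    abort("read counts must be non-negative")
  }
  if (any(snvs$variant_reads > snvs$total_reads, na.rm = TRUE)) {
    abort("variant reads cannot exceed total reads")
  }
  if (!"error_profile" %in% names(snvs)) snvs$error_profile <- FALSE
  if (!"regions" %in% names(snvs)) {
    snvs$regions <- rep(list(character(0)), nrow(snvs))
  }

  vaf <- snvs$variant_reads / snvs$total_reads
  single_strand <- (snvs$forward_variant_reads == 0 |
                      snvs$reverse_variant_reads == 0) &
    snvs$variant_reads > 0
  control_missing <- is.na(snvs$control_coverage) |
    is.na(snvs$control_variant_bases)
  control_fraction <- snvs$control_variant_bases / snvs$control_coverage

  fails <- list(
    min_variant_reads = snvs$variant_reads < min_variant_reads,
    min_vaf = !(vaf >= min_vaf),
    strand_error_profile = single_strand & isTRUE_vec(snvs$error_profile),
    control_coverage = snvs$control_coverage < min_control_coverage,
    control_variant_fraction = !(control_fraction < max_control_fraction),
    mappability_blacklist = purrr::map_lgl(
      snvs$regions, ~ any(.x %in% .blacklist_classes)),
    repeat_overlap = purrr::map_lgl(
      snvs$regions, ~ sum(unique(.x) %in% .repeat_classes) >= 2)
  )
  rule_order <- snv_filter_rules()
  snvs$failed_rules <- purrr::map(seq_len(nrow(snvs)), function(i) {
    rule_order[vapply(fails[rule_order], function(f) isTRUE(f[i]),
                      logical(1))]
  })
  snvs$pass <- lengths(snvs$failed_rules) == 0
  snvs$pass[control_missing] <- NA
  snvs
}

#' Flag-based filtering of candidate small indels
#'
#' Somatic indel candidates (control genotype `0/0`) pass when their
#' caller FILTER flag is `PASS`; candidates flagged `badReads`,
#' `alleleBias` or `strandBias` are discarded when the variant allele
#' frequency is below 0.10. Calls with a non-reference control genotype
#' fail as germline. Unrecognized filter flags are retained with a
#' warning (they never auto-fail a call).
#'
#' @param indels Data frame with columns `filter` (FILTER string,
#'   semicolon-separated flags), `control_genotype` (e.g. `"0/0"`) and
#'   either `vaf` or `variant_reads`/`total_reads`.
#' @param max_flag_vaf VAF below which the flagged calls are discarded
#'   (exclusive; default 0.10).
#' @return The input with `failed_rules` (list column) and `pass`.
#' @export
filter_indel <- function(indels, max_flag_vaf = 0.10) {
  indels <- as_tibble(indels)
  stopifnot(all(c("filter", "control_genotype") %in% names(indels)))
  if (!"vaf" %in% names(indels)) {
    stopifnot(all(c("variant_reads", "total_reads") %in% names(indels)))
    indels$vaf <- indels$variant_reads / indels$total_reads
  }
  bias_flags <- c("badReads", "alleleBias", "strandBias")
  flags <- strsplit(as.character(indels$filter), "[;,]")
  known <- c("PASS", ".", bias_flags)
  unknown <- setdiff(unique(unlist(flags)), known)
  if (length(unknown) > 0) {
    warn(paste0("unrecognized filter flag(s) retained: ",
                paste(unknown, collapse = ", ")))
  }
  not_somatic <- indels$control_genotype != "0/0"
  has_pass <- purrr::map_lgl(flags, ~ "PASS" %in% .x)
  has_bias <- purrr::map_lgl(flags, ~ any(.x %in% bias_flags))
  flagged_low_vaf <- !has_pass & has_bias & indels$vaf < max_flag_vaf
  indels$failed_rules <- purrr::map(seq_len(nrow(indels)), function(i) {
    c(if (not_somatic[i]) "not_somatic",
      if (!not_somatic[i] && flagged_low_vaf[i]) "flagged_low_vaf")
  })
  indels$pass <- lengths(indels$failed_rules) == 0
  indels
}

#' Annotate variants with overlapping region classes
#'
#' Overlaps each variant position with named interval sets (0-based
#' half-open, BED convention); a variant at 1-based position `pos`
#' overlaps interval `[start, end)` when `pos - 1` lies inside it.
#'
#' @param variants Data frame with columns `chrom`, `pos` (1-based).
#' @param region_sets Named list of data frames, each with columns
#'   `chrom`, `start`, `end`. The names are the region classes (e.g.
#'   `"blacklist"`, `"simple-repeat"`).
#' @return `variants` with a `regions` list column holding, per variant,
#'   the names of every overlapping region set.
#' @export
annotate_regions <- function(variants, region_sets) {
  variants <- as_tibble(variants)
  stopifnot(all(c("chrom", "pos") %in% names(variants)))
  if (is.null(names(region_sets)) || any(names(region_sets) == "")) {
    abort("`region_sets` must be a named list")
  }
  hits <- matrix(FALSE, nrow = nrow(variants), ncol = length(region_sets),
                 dimnames = list(NULL, names(region_sets)))
  pos0 <- variants$pos - 1
  for (nm in names(region_sets)) {
    bed <- as_tibble(region_sets[[nm]])
    if (!all(c("chrom", "start", "end") %in% names(bed))) {
      abort(paste0("region set '", nm, "' lacks chrom/start/end columns"))
    }
    bad <- is.na(bed$start) | is.na(bed$end) | bed$end < bed$start
    if (any(bad)) {
      abort(paste0("malformed interval in region set '", nm, "' at line ",
                   which(bad)[1]))
    }
    for (i in seq_len(nrow(variants))) {
      sub <- bed[bed$chrom == variants$chrom[i], ]
      hits[i, nm] <- any(pos0[i] >= sub$start & pos0[i] < sub$end)
    }
  }
  variants$regions <- purrr::map(seq_len(nrow(variants)), function(i) {
    names(region_sets)[hits[i, ]]
  })
  variants
}

#' Flag sequencing error-profile contexts around variants
#'
#' Marks variants whose surrounding sequence (a window of +/- `window`
#' bases) matches any of a user-supplied set of error-profile patterns
#' (regular expressions). An empty pattern set flags nothing, which
#' disables the single-strand/error-profile filter rule.
#'
#' @param snvs Data frame with a `context_seq` column holding the window
#'   sequence around each variant.
#' @param patterns Character vector of regular expressions (default
#'   empty).
#' @return `snvs` with an `error_profile` logical column.
#' @export
flag_error_profiles <- function(snvs, patterns = character(0)) {
  snvs <- as_tibble(snvs)
  stopifnot("context_seq" %in% names(snvs))
  if (length(patterns) == 0) {
    snvs$error_profile <- FALSE
    return(snvs)
  }
  snvs$error_profile <- purrr::map_lgl(toupper(snvs$context_seq), function(s) {
    any(vapply(patterns, function(p) grepl(p, s), logical(1)))
  })
  snvs
}
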