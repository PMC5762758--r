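#' Copy-number genotype classes
#'
#' @return Character vector of the recognized classes.
#' @export
cn_classes <- function() {
  c("normal_biallelic", "LOH", "CNN_LOH", "higher_ploidy_LOH",
    "homozygous_deletion")
}

#' Classify allele-specific copy number into genotype classes
#'
#' Cases retaining a single allele (`major = 1, minor = 0`) are
#' loss-of-heterozygosity (LOH); two or more copies all derived from the
#' same parental allele are copy-number-neutral LOH (`major = 2,
#' minor = 0`) or higher-ploidy LOH (`major >= 3, minor = 0`); retention
#' of both parental alleles (`minor >= 1`) is the normal / biallelic-
#' alteration group; `(0, 0)` is a homozygous deletion (biallelic
#' inactivation by deletion alone).
#'
#' @param acn Data frame with columns `major_cn` and `minor_cn`
#'   (non-negative integers, `major_cn >= minor_cn`).
#' @return The input with a `cn_class` column (see [cn_classes()]).
#' @export
#' @examples
#' classify_cn(tibble::tibble(major_cn = c(1, 2, 2), minor_cn = c(0, 0, 1)))
classify_cn <- function(acn) {
  acn <- as_tibble(acn)
  stopifnot(all(c("major_cn", "minor_cn") %in% names(acn)))
  if (any(acn$major_cn < 0 | acn$minor_cn < 0)) {
    abort("copy numbers must be non-negative")
  }
  if (any(acn$major_cn < acn$minor_cn)) {
    abort("major_cn must be >= minor_cn")
  }
  acn$cn_class <- dplyr::case_when(
    acn$major_cn == 0 & acn$minor_cn == 0 ~ "homozygous_deletion",
    acn$minor_cn >= 1 ~ "normal_biallelic",
    acn$major_cn == 1 ~ "LOH",
    acn$major_cn == 2 ~ "CNN_LOH",
    TRUE ~ "higher_ploidy_LOH"
  )
  acn
}

#' Recognized lesion types
#' @return Character vector.
#' @export
lesion_types <- function() {
  c("SNV", "indel", "fusion", "microalteration", "germline", "deletion")
}

#' Flag biallelic inactivation from copy-number class and lesions
#'
#' Integrates per-gene allele-specific copy number with the list of
#' lesions hitting the gene. A gene is biallelically inactivated when
#' (a) it is homozygously deleted, or (b) a single parental allele is
#' retained (`minor_cn = 0`) and at least one damaging lesion hits the
#' retained allele, or (c) both alleles are retained and damaging lesions
#' are assigned to both. Lesions with unknown allele in an LOH context
#' are assumed to sit on the retained allele, unless a variant allele
#' fraction is supplied that is incongruent with the tumor purity
#' ([vaf_purity_congruence()]); lesions assigned to the lost allele are
#' ignored with a warning. For genes on chromosome X in male samples a
#' single damaging lesion suffices (hemizygous genes have no second copy).
#'
#' @param acn Per sample x gene allele-specific copy number: columns
#'   `sample`, `gene`, `major_cn`, `minor_cn`, optionally `chrom` and
#'   `purity`.
#' @param lesions Lesion table: columns `sample`, `gene`, `lesion_type`
#'   (see [lesion_types()]), `damaging` (logical), optionally `allele`
#'   (`"A"`, `"B"` or `"unknown"`; the retained allele of an LOH gene is
#'   `"A"` by convention) and `vaf`.
#' @param metadata Optional per-sample table with columns `sample` and
#'   `sex` (`"male"`/`"female"`), used for the chromosome-X rule.
#' @param vaf_tolerance Tolerance for VAF/purity congruence (default 0.1).
#' @return Tibble with one row per sample x gene: `cn_class`,
#'   `biallelic_inactivation` and an `evidence` string.
#' @export
flag_biallelic <- function(acn, lesions, metadata = NULL,
                           vaf_tolerance = 0.1) {
  acn <- classify_cn(acn)
  stopifnot(all(c("sample", "gene") %in% names(acn)))
  lesions <- as_tibble(lesions)
  stopifnot(all(c("sample", "gene", "lesion_type", "damaging") %in%
                  names(lesions)))
  unknown_type <- setdiff(unique(lesions$lesion_type), lesion_types())
  if (length(unknown_type) > 0) {
    abort(paste0("unknown lesion type(s): ",
                 paste(unknown_type, collapse = ", ")))
  }
  if (!"allele" %in% names(lesions)) lesions$allele <- "unknown"
  lesions$allele[is.na(lesions$allele)] <- "unknown"
  if (!"vaf" %in% names(lesions)) lesions$vaf <- NA_real_
  if (!is.null(metadata)) {
    acn <- dplyr::left_join(acn, as_tibble(metadata)[c("sample", "sex")],
                            by = "sample")
  }
  if (!"sex" %in% names(acn)) acn$sex <- NA_character_
  if (!"chrom" %in% names(acn)) acn$chrom <- NA_character_
  if (!"purity" %in% names(acn)) acn$purity <- NA_real_

  purrr::pmap_dfr(
    acn[c("sample", "gene", "major_cn", "minor_cn", "cn_class", "chrom",
          "sex", "purity")],
    function(sample, gene, major_cn, minor_cn, cn_class, chrom, sex, purity) {
      les <- lesions[lesions$sample == sample & lesions$gene == gene, ]
      dmg <- les[isTRUE_vec(les$damaging), ]
      hemizygous <- !is.na(chrom) && chrom %in% c("X", "chrX") &&
        !is.na(sex) && sex == "male"
      evidence <- character(0)
      flag <- FALSE
      if (cn_class == "homozygous_deletion") {
        flag <- TRUE
        evidence <- "homozygous deletion"
      } else if (hemizygous) {
        flag <- nrow(dmg) > 0
        if (flag) evidence <- c("hemizygous (chrX, male)",
                                lesion_labels(dmg))
      } else if (minor_cn == 0) {
        ## single parental allele retained ("A" by convention)
        on_lost <- dmg$allele == "B"
        if (any(on_lost)) {
          warn(paste0(sum(on_lost), " damaging lesion(s) in ", sample, "/",
                      gene, " assigned to the lost allele; ignored"))
        }
        usable <- dmg[!on_lost, , drop = FALSE]
        on_retained <- usable$allele == "A" |
          (usable$allele == "unknown" &
             unknown_on_retained(usable$vaf, purity, major_cn, minor_cn,
                                 vaf_tolerance))
        flag <- any(on_retained)
        if (flag) {
          evidence <- c(paste0(cn_class, " (single allele retained)"),
                        lesion_labels(usable[on_retained, , drop = FALSE]))
        }
      } else {
        ## both parental alleles present: need damaging hits on both
        flag <- any(dmg$allele == "A") && any(dmg$allele == "B")
        if (flag) evidence <- lesion_labels(dmg[dmg$allele %in% c("A", "B"), ])
      }
      tibble(sample = sample, gene = gene, major_cn = major_cn,
             minor_cn = minor_cn, cn_class = cn_class,
             biallelic_inactivation = flag,
             evidence = paste(evidence, collapse = "; "))
    }
  )
}

isTRUE_vec <- function(x) !is.na(x) & x

lesion_labels <- function(les) {
  if (nrow(les) == 0) return(character(0))
  paste0(les$lesion_type, ifelse(les$allele %in% c("A", "B"),
                                 paste0(" (allele ", les$allele, ")"), ""))
}

## unknown-allele lesion counts as on the retained allele unless its VAF
## clearly contradicts the purity expectation
unknown_on_retained <- function(vaf, purity, major_cn, minor_cn, tol) {
  if (length(vaf) == 0) return(logical(0))
  no_info <- is.na(vaf) | is.na(purity)
  out <- rep(TRUE, length(vaf))
  idx <- which(!no_info)
  if (length(idx) > 0) {
    cong <- vaf_purity_congruence(vaf[idx], purity, major_cn, minor_cn,
                                  tolerance = tol)
    out[idx] <- cong$congruent
  }
  out
}

#' Expected variant allele fraction under a purity/copy-number model
#'
#' For a clonal mutation on `mutated_copies` of the tumor's
#' `major_cn + minor_cn` copies, in a tumor of the given purity admixed
#' with diploid normal cells, the expected VAF is
#' `purity * mutated_copies / (purity * (major_cn + minor_cn) +
#' 2 * (1 - purity))`. Under the retained-allele model for LOH genes,
#' `mutated_copies = major_cn`. Observed VAFs within `tolerance` of the
#' expectation are congruent with purity, supporting a truncal mutation
#' on the retained allele.
#'
#' @param vaf Observed variant allele fraction(s).
#' @param purity Tumor purity in (0, 1].
#' @param major_cn,minor_cn Allele-specific copy numbers (total must be
#'   positive).
#' @param mutated_copies Copies carrying the mutation (default
#'   `major_cn`).
#' @param tolerance Absolute VAF tolerance (default 0.1).
#' @return Tibble with columns `expected_vaf` and `congruent`.
#' @export
#' @examples
#' vaf_purity_congruence(0.35, purity = 0.5, major_cn = 1, minor_cn = 0)
vaf_purity_congruence <- function(vaf, purity, major_cn, minor_cn,
                                  mutated_copies = major_cn,
                                  tolerance = 0.1) {
  if (any(purity <= 0 | purity > 1)) abort("purity must lie in (0, 1]")
  if (any(major_cn < 0 | minor_cn < 0)) abort("copy numbers must be non-negative")
  total <- major_cn + minor_cn
  if (any(total == 0)) abort("total copy number 0: expected VAF undefined")
  expected <- purity * mutated_copies / (purity * total + 2 * (1 - purity))
  tibble(expected_vaf = expected,
         congruent = abs(vaf - expected) <= tolerance)
}

#' Call whole-genome duplication from allele-specific copy number
#'
#' Whole-genome duplication (tetraploidization) leaves most of the genome
#' with at least two copies of the major parental allele and an elevated
#' overall ploidy. The call is positive when the estimated ploidy is at
#' least `min_ploidy` and the length-weighted fraction of the assessable
#' genome with `major_cn >= 2` exceeds `min_major_fraction`.
#'
#' @param segments Genome-wide allele-specific copy-number segments:
#'   columns `sample`, `major_cn`, `minor_cn` and either `start`/`end`
#'   (1-based inclusive) or a `length` column.
#' @param ploidy Per-sample ploidy: tibble with columns `sample`,
#'   `ploidy`, or a single number applied to all samples.
#' @param min_ploidy Ploidy threshold (default 2.9).
#' @param min_major_fraction Required genome fraction with major copy
#'   >= 2, exclusive (default 0.5).
#' @param assessable_size Total assessable genome size in the same units
#'   as the segment lengths. When supplied, samples whose segments cover
#'   less than `min_coverage` of it are reported as not determined
#'   (`wgd = NA`).
#' @param min_coverage Minimum segment coverage of the assessable genome
#'   (default 0.5).
#' @return Tibble with one row per sample: `ploidy`,
#'   `fraction_major_ge2`, `coverage`, `wgd` (logical; `NA` = not
#'   determined).
#' @export
call_wgd <- function(segments, ploidy, min_ploidy = 2.9,
                     min_major_fraction = 0.5, assessable_size = NULL,
                     min_coverage = 0.5) {
  segments <- as_tibble(segments)
  stopifnot(all(c("sample", "major_cn", "minor_cn") %in% names(segments)))
  if (!"length" %in% names(segments)) {
    if (!all(c("start", "end") %in% names(segments))) {
      abort("segments need `length` or `start`/`end` columns")
    }
    segments$length <- segments$end - segments$start + 1
  }
  if (is.numeric(ploidy) && is.null(dim(ploidy)) && length(ploidy) == 1) {
    ploidy <- tibble(sample = unique(segments$sample), ploidy = ploidy)
  }
  ploidy <- as_tibble(ploidy)
  stopifnot(all(c("sample", "ploidy") %in% names(ploidy)))

  segments |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      covered = sum(.data$length),
      fraction_major_ge2 = sum(.data$length[.data$major_cn >= 2]) /
        sum(.data$length),
      .groups = "drop"
    ) |>
    dplyr::left_join(ploidy, by = "sample") |>
    dplyr::mutate(
      coverage = if (is.null(assessable_size)) 1 else
        .data$covered / assessable_size,
      wgd = dplyr::if_else(
        .data$coverage < min_coverage, NA,
        .data$ploidy >= min_ploidy &
          .data$fraction_major_ge2 > min_major_fraction
      )
    ) |>
    dplyr::select("sample", "ploidy", "fraction_major_ge2", "coverage",
                  "wgd")
}
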