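#' Configuration for synthetic cohort generation
#'
#' Bundles and validates the parameters shared by the synthetic-data
#' generators. A fixed seed makes every generator bit-identical across
#' runs.
#'
#' @param seed Integer random seed.
#' @param n_samples Number of samples in the cohort.
#' @param signature_mix Named numeric vector of true relative exposures
#'   (signature id -> fraction); non-negative, summing to at most 1.
#' @param mutations_per_sample Expected somatic mutation count per sample
#'   (must be positive).
#' @param chromothripsis_fraction Proportion of samples carrying a
#'   chromothriptic chromosome, in `[0, 1]`.
#' @param wgd_fraction Proportion of samples with whole-genome
#'   duplication, in `[0, 1]`.
#' @param noise_model `"multinomial"` (fixed total per sample, the
#'   default) or `"poisson"` (totals vary around the expectation, as real
#'   mutation burdens do).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1, n_samples = 50,
                       signature_mix = c(S1 = 0.5, S2 = 0.3, S3 = 0.2),
                       mutations_per_sample = 2000,
                       chromothripsis_fraction = 0.35,
                       wgd_fraction = 0.55,
                       noise_model = c("multinomial", "poisson")) {
  noise_model <- match.arg(noise_model)
  if (length(seed) != 1 || is.na(seed)) abort("`seed` must be one integer")
  if (n_samples < 1) abort("`n_samples` must be at least 1")
  if (is.null(names(signature_mix)) || any(names(signature_mix) == "")) {
    abort("`signature_mix` must be a named vector")
  }
  if (any(signature_mix < 0)) abort("true relative exposures must be non-negative")
  if (sum(signature_mix) > 1 + 1e-9) abort("`signature_mix` must sum to at most 1")
  if (mutations_per_sample <= 0) abort("`mutations_per_sample` must be positive")
  for (p in c(chromothripsis_fraction, wgd_fraction)) {
    if (p < 0 || p > 1) abort("proportions must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 signature_mix = signature_mix,
                 mutations_per_sample = mutations_per_sample,
                 chromothripsis_fraction = chromothripsis_fraction,
                 wgd_fraction = wgd_fraction, noise_model = noise_model),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_samples, "samples |",
      x$mutations_per_sample, "mutations/sample |", x$noise_model,
      "noise\n")
  cat("mix:", paste(names(x$signature_mix), signif(x$signature_mix, 3),
                    sep = "=", collapse = ", "), "\n")
  invisible(x)
}

sim_sample_ids <- function(n) sprintf("SIM%03d", seq_len(n))

#' Simulate mutational catalogs from a known signature mixture
#'
#' Draws each sample's 96-context count vector with expectation
#' `mutations_per_sample * W %*% mix`. Under multinomial noise the total
#' per sample is exactly `mutations_per_sample`; under Poisson noise each
#' context count is an independent Poisson draw, so totals vary around
#' the expectation, as real mutation burdens do. A mixture summing to
#' less than 1 is renormalized (the truth table records the normalized
#' relative exposures).
#'
#' @param config A [sim_config()]; `signature_mix` names must be
#'   signatures of `sigs`.
#' @param sigs A `"signature_set"`.
#' @return List with `catalog` (wide catalog tibble) and `truth` (tibble:
#'   `sample`, `signature`, `true_rel_exposure`, `true_exposure` expected
#'   counts).
#' @export
simulate_catalogs <- function(config, sigs) {
  stopifnot(inherits(config, "sim_config"), inherits(sigs, "signature_set"))
  mix <- config$signature_mix
  unknown <- setdiff(names(mix), colnames(sigs$w))
  if (length(unknown) > 0) {
    abort(paste0("signature_mix contains unknown signature(s): ",
                 paste(unknown, collapse = ", ")))
  }
  mix <- mix / sum(mix)
  p <- as.numeric(sigs$w[, names(mix), drop = FALSE] %*% mix)
  n_mut <- config$mutations_per_sample
  ids <- sim_sample_ids(config$n_samples)
  mat <- withr::with_seed(config$seed, {
    if (config$noise_model == "multinomial") {
      rmultinom(config$n_samples, size = n_mut, prob = p)
    } else {
      matrix(rpois(96 * config$n_samples, lambda = rep(n_mut * p,
                                                       config$n_samples)),
             nrow = 96)
    }
  })
  rownames(mat) <- rownames(sigs$w)
  colnames(mat) <- ids
  truth <- tidyr::expand_grid(sample = ids, signature = names(mix)) |>
    dplyr::mutate(true_rel_exposure = mix[.data$signature],
                  true_exposure = n_mut * mix[.data$signature])
  list(catalog = new_catalog(mat), truth = truth)
}

#' Simulate segmented copy-number profiles with and without chromothripsis
#'
#' Each sample gets one synthetic 250-Mb pseudo-chromosome. Positive
#' samples (a `chromothripsis_fraction` share of the cohort) carry a run
#' of exactly `n_switches` alternating switches between integer states 2
#' and 1 whose first and last breakpoints are exactly `span_mb` apart;
#' negative samples are flat or carry a sparse sub-threshold pattern
#' (fewer than 6 switches, at low density).
#'
#' @param config A [sim_config()].
#' @param n_switches Alternating switches on positive chromosomes
#'   (default 10).
#' @param span_mb Span between first and last breakpoint on positive
#'   chromosomes in Mb (default 50).
#' @param chrom_length_mb Pseudo-chromosome length (default 250).
#' @return List with `segments` (tibble: `sample`, `chrom`, `start`,
#'   `end`, `log2`, `state`) and `truth` (tibble: `sample`, `chrom`,
#'   `chromothripsis`).
#' @export
simulate_profiles <- function(config, n_switches = 10, span_mb = 50,
                              chrom_length_mb = 250) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  ids <- sim_sample_ids(n)
  chrom_len <- chrom_length_mb * 1e6
  withr::with_seed(config$seed + 1L, {
    positive <- runif(n) < config$chromothripsis_fraction
    segments <- purrr::map_dfr(seq_len(n), function(i) {
      if (positive[i]) {
        seg <- oscillating_segments(n_switches, span_mb * 1e6, chrom_len)
      } else {
        k <- sample(0:5, 1)   # sparse: < 6 switches, low density
        seg <- if (k == 0) {
          tibble(start = 1, end = chrom_len, state = 2)
        } else {
          oscillating_segments(k, max(k, 2) / 0.1 * 1e6, chrom_len)
        }
      }
      seg$sample <- ids[i]
      seg$chrom <- "chr_sim"
      seg$log2 <- log2(pmax(seg$state, 0.5) / 2)
      seg[c("sample", "chrom", "start", "end", "log2", "state")]
    })
    truth <- tibble(sample = ids, chrom = "chr_sim",
                    chromothripsis = positive)
    list(segments = segments, truth = truth)
  })
}

## build segments with exactly k alternating 2/1 switches whose first and
## last breakpoints are exactly span apart, placed at a random offset
oscillating_segments <- function(k, span, chrom_len) {
  stopifnot(k >= 1)
  b1 <- if (chrom_len - span > 2e6) {
    floor(runif(1, 1e6, chrom_len - span - 1e6))
  } else {
    1e6
  }
  if (k == 1) {
    bp <- b1
  } else {
    bp <- round(b1 + (seq_len(k) - 1) * span / (k - 1))
    bp[1] <- b1
    bp[k] <- b1 + span
  }
  bounds <- c(0, bp, chrom_len)     # segment i covers (bounds[i], bounds[i+1]]
  states <- rep(c(2, 1), length.out = k + 1)
  tibble(start = bounds[-length(bounds)] + 1,
         end = bounds[-1],
         state = states)
}

#' Simulate C-circle and telomere-qPCR tables with known ALT status
#'
#' ALT-positive samples (default prevalence 0.78, the observed cohort
#' frequency) receive C-circle intensity triplets satisfying both
#' classification thresholds (signal at least twofold the no-polymerase
#' control and threefold the background); negative samples violate at
#' least one. Telomere-content log2 ratios are drawn independently of ALT
#' status, reflecting the observed lack of correlation between the two.
#'
#' @param config A [sim_config()].
#' @param alt_fraction ALT prevalence (default 0.78).
#' @return List with `ccircle` (sample, intensity_pol, intensity_nopol,
#'   background), `qpcr` (sample, tumor_t, tumor_s, control_t,
#'   control_s) and `truth` (sample, alt).
#' @export
simulate_telomere_tables <- function(config, alt_fraction = 0.78) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  ids <- sim_sample_ids(n)
  withr::with_seed(config$seed + 2L, {
    alt <- runif(n) < alt_fraction
    background <- runif(n, 0.5, 1.5)
    nopol <- background * runif(n, 0.8, 1.5)
    floor_pos <- pmax(2 * nopol, 3 * background)
    pol <- ifelse(alt,
                  floor_pos * runif(n, 1.2, 3),
                  pmin(2 * nopol, 3 * background) * runif(n, 0.3, 0.95))
    ccircle <- tibble(sample = ids, intensity_pol = pol,
                      intensity_nopol = nopol, background = background)
    control_s <- runif(n, 0.8, 1.2)
    control_t <- control_s * runif(n, 0.5, 2)
    tumor_s <- runif(n, 0.8, 1.2)
    log2_shift <- rnorm(n, 0, 1.5)
    tumor_t <- tumor_s * (control_t / control_s) * 2^log2_shift
    qpcr <- tibble(sample = ids, tumor_t = tumor_t, tumor_s = tumor_s,
                   control_t = control_t, control_s = control_s)
    list(ccircle = ccircle, qpcr = qpcr,
         truth = tibble(sample = ids, alt = alt))
  })
}

#' Simulate gene lesions and allele-specific copy number with known classes
#'
#' Emits, per sample and gene, an allele-specific copy-number
#' configuration drawn to cover all five genotype classes across the
#' cohort, together with lesions consistent with a chosen
#' biallelic-inactivation truth. A `wgd_fraction` share of samples is
#' tetraploid (ploidy near 4, most chromosomes with major copy >= 2);
#' the rest are diploid.
#'
#' @param config A [sim_config()].
#' @param genes Gene names (default four canonical tumor suppressors).
#' @return List with `lesions`, `allele_cn` (per sample x gene),
#'   `segments` (genome-wide, for [call_wgd()]), `metadata` (sample, sex,
#'   purity, ploidy) and `truth` (per sample x gene class and biallelic
#'   flag plus per-sample `wgd`).
#' @export
simulate_genotypes <- function(config,
                               genes = c("TP53", "RB1", "PTEN", "ATRX")) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  ids <- sim_sample_ids(n)
  classes <- cn_classes()
  withr::with_seed(config$seed + 3L, {
    wgd <- runif(n) < config$wgd_fraction
    grid <- tidyr::expand_grid(sample = ids, gene = genes)
    ## cycle classes so every class is represented
    grid$cn_class_true <- classes[(seq_len(nrow(grid)) - 1) %% 5 + 1]
    cn_for_class <- function(cls) {
      switch(cls,
             normal_biallelic = c(sample(1:2, 1), 1),
             LOH = c(1, 0),
             CNN_LOH = c(2, 0),
             higher_ploidy_LOH = c(sample(3:4, 1), 0),
             homozygous_deletion = c(0, 0))
    }
    cns <- t(vapply(grid$cn_class_true, cn_for_class, numeric(2)))
    grid$major_cn <- cns[, 1]
    grid$minor_cn <- cns[, 2]
    ## biallelic truth: hom-del always; LOH-type genes get a damaging
    ## lesion on the retained allele half the time; normal genes get
    ## damaging lesions on both alleles a third of the time
    grid$biallelic_true <- dplyr::case_when(
      grid$cn_class_true == "homozygous_deletion" ~ TRUE,
      grid$cn_class_true == "normal_biallelic" ~ runif(nrow(grid)) < 1 / 3,
      TRUE ~ runif(nrow(grid)) < 0.5
    )
    lesions <- purrr::pmap_dfr(
      grid[c("sample", "gene", "cn_class_true", "biallelic_true")],
      function(sample, gene, cn_class_true, biallelic_true) {
        if (cn_class_true == "homozygous_deletion") {
          return(tibble(sample = sample, gene = gene,
                        lesion_type = "deletion", allele = "unknown",
                        damaging = TRUE))
        }
        if (!biallelic_true) {
          ## at most a harmless or single-allele lesion
          if (runif(1) < 0.5) return(tibble(
            sample = character(0), gene = character(0),
            lesion_type = character(0), allele = character(0),
            damaging = logical(0)))
          return(tibble(sample = sample, gene = gene, lesion_type = "SNV",
                        allele = "A",
                        damaging = cn_class_true == "normal_biallelic"))
        }
        if (cn_class_true == "normal_biallelic") {
          return(tibble(sample = sample, gene = gene,
                        lesion_type = c("SNV", sample(c("indel", "fusion"), 1)),
                        allele = c("A", "B"), damaging = TRUE))
        }
        tibble(sample = sample, gene = gene,
               lesion_type = sample(c("SNV", "indel"), 1), allele = "A",
               damaging = TRUE)
      }
    )
    allele_cn <- grid[c("sample", "gene", "major_cn", "minor_cn")]
    ## genome-wide segments: 22 pseudo-chromosomes
    chrom_len <- round(seq(250, 50, length.out = 22)) * 1e6
    segments <- purrr::map_dfr(seq_len(n), function(i) {
      major <- if (wgd[i]) {
        ifelse(runif(22) < 0.85, 2, 3)
      } else {
        ifelse(runif(22) < 0.85, 1, 2)
      }
      minor <- pmin(major, if (wgd[i]) 2 else 1)
      tibble(sample = ids[i], chrom = paste0("chr", 1:22), start = 1,
             end = chrom_len, major_cn = major, minor_cn = minor)
    })
    ploidy_tbl <- segments |>
      dplyr::group_by(.data$sample) |>
      dplyr::summarise(ploidy = sum((.data$major_cn + .data$minor_cn) *
                                      (.data$end - .data$start + 1)) /
                         sum(.data$end - .data$start + 1),
                       .groups = "drop")
    metadata <- tibble(sample = ids,
                       sex = sample(c("male", "female"), n, replace = TRUE),
                       purity = runif(n, 0.4, 0.95)) |>
      dplyr::left_join(ploidy_tbl, by = "sample")
    truth <- grid[c("sample", "gene", "cn_class_true", "biallelic_true")] |>
      dplyr::left_join(tibble(sample = ids, wgd = wgd), by = "sample")
    list(lesions = lesions, allele_cn = allele_cn, segments = segments,
         metadata = metadata, truth = truth)
  })
}

#' Write a simulated cohort to TSV files
#'
#' Writes every table produced by the simulators (and the truth tables,
#' always alongside the data, never inferred) into a directory.
#'
#' @param sim A named list of data frames (e.g. the result of a
#'   simulator, or several results concatenated).
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_simdata <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(sim)) {
    x <- sim[[nm]]
    if (!is.data.frame(x)) next
    path <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
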