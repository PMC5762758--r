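test_that("sim_config validates its parameters", {
  cfg <- sim_config(seed = 7, n_samples = 3)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$seed, 7L)
  expect_error(sim_config(mutations_per_sample = 0), "positive")
  expect_error(sim_config(signature_mix = c(S1 = -0.1, S2 = 1.1)),
               "non-negative")
  expect_error(sim_config(signature_mix = c(S1 = 0.9, S2 = 0.2)),
               "at most 1")
  expect_error(sim_config(signature_mix = c(0.5, 0.5)), "named")
  expect_error(sim_config(chromothripsis_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(noise_model = "gaussian"))
})

test_that("catalog simulation is deterministic and respects totals", {
  sigs <- random_signature_set(3, seed = 5)
  cfg <- sim_config(seed = 42, n_samples = 8,
                    signature_mix = c(S1 = 0.5, S2 = 0.3, S3 = 0.2),
                    mutations_per_sample = 1500)
  a <- simulate_catalogs(cfg, sigs)
  b <- simulate_catalogs(cfg, sigs)
  expect_identical(a, b)

  m <- catalog_matrix(a$catalog)
  expect_equal(dim(m), c(96, 8))
  expect_equal(unname(colSums(m)), rep(1500, 8))  # multinomial: exact totals
  expect_equal(colnames(m), sprintf("SIM%03d", 1:8))
  expect_equal(unique(a$truth$true_rel_exposure[a$truth$signature == "S1"]),
               0.5)

  ## a different seed gives different draws
  c2 <- simulate_catalogs(sim_config(seed = 43, n_samples = 8,
                                     mutations_per_sample = 1500), sigs)
  expect_false(identical(catalog_matrix(c2$catalog), m))

  ## poisson noise: totals vary around the expectation
  pois <- simulate_catalogs(sim_config(seed = 42, n_samples = 30,
                                       mutations_per_sample = 1500,
                                       noise_model = "poisson"), sigs)
  tot <- colSums(catalog_matrix(pois$catalog))
  expect_false(all(tot == 1500))
  expect_lt(abs(mean(tot) - 1500), 5 * sqrt(1500 / 30))

  expect_error(
    simulate_catalogs(sim_config(signature_mix = c(S9 = 1)), sigs),
    "unknown signature"
  )
})

test_that("a single-signature cohort reproduces that signature's profile", {
  sigs <- random_signature_set(3, seed = 5)
  cfg <- sim_config(seed = 2, n_samples = 1,
                    signature_mix = c(S2 = 1), mutations_per_sample = 50000)
  sim <- simulate_catalogs(cfg, sigs)
  freq <- catalog_matrix(sim$catalog)[, 1] / 50000
  ## 50k multinomial draws: per-context sd <= 0.0023, so 0.01 is > 4 sd
  expect_lt(max(abs(freq - sigs$w[, "S2"])), 0.01)

  ## a mixture summing to < 1 is renormalized in the recorded truth
  half <- sim_config(seed = 2, n_samples = 2,
                     signature_mix = c(S1 = 0.3, S2 = 0.2))
  tr <- simulate_catalogs(half, sigs)$truth
  expect_equal(sort(unique(tr$true_rel_exposure)), c(0.4, 0.6))
})

test_that("decomposition recovers the simulated mixture on average", {
  sigs <- random_signature_set(3, seed = 5)
  cfg <- sim_config(seed = 3, n_samples = 10,
                    signature_mix = c(S1 = 0.6, S2 = 0.4),
                    mutations_per_sample = 5000)
  sim <- simulate_catalogs(cfg, sigs)
  fit <- supervised_decompose(sim$catalog, sigs, ci = FALSE)
  rel <- tidy(fit) |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(m = mean(.data$rel_exposure), .groups = "drop")
  expect_lt(abs(rel$m[rel$signature == "S1"] - 0.6), 0.05)
  expect_lt(abs(rel$m[rel$signature == "S2"] - 0.4), 0.05)
  expect_lt(rel$m[rel$signature == "S3"], 0.05)
})

test_that("profile simulation labels are recovered exactly by the caller", {
  cfg <- sim_config(seed = 11, n_samples = 40, chromothripsis_fraction = 0.35)
  sim <- simulate_profiles(cfg)
  expect_identical(sim, simulate_profiles(cfg))  # deterministic
  expect_silent(validate_segments(sim$segments))

  calls <- call_chromothripsis(sim$segments)
  joined <- dplyr::left_join(sim$truth, calls, by = c("sample", "chrom"))
  expect_equal(joined$positive, joined$chromothripsis)
  ## positive chromosomes sit exactly at the density threshold by design
  expect_equal(unique(joined$ratio[joined$chromothripsis]), 0.2)
  expect_equal(unique(joined$n_switches[joined$chromothripsis]), 10)

  ## degenerate fractions
  all_pos <- simulate_profiles(sim_config(seed = 12, n_samples = 6,
                                          chromothripsis_fraction = 1))
  expect_true(all(all_pos$truth$chromothripsis))
  none <- simulate_profiles(sim_config(seed = 12, n_samples = 6,
                                       chromothripsis_fraction = 0))
  expect_false(any(none$truth$chromothripsis))
  expect_false(any(call_chromothripsis(none$segments)$positive))
})

test_that("telomere simulation round-trips through the ALT classifier", {
  cfg <- sim_config(seed = 21, n_samples = 60)
  sim <- simulate_telomere_tables(cfg)
  expect_identical(sim, simulate_telomere_tables(cfg))

  cls <- classify_alt(sim$ccircle)
  expect_false(any(cls$status == "not_determined"))
  expect_equal(cls$status == "positive", sim$truth$alt)

  ## qPCR tables are well-formed for ts_ratio
  ts <- ts_ratio(sim$qpcr)
  expect_true(all(is.finite(ts$log2_ratio)))
})

test_that("genotype simulation round-trips through classification and WGD", {
  cfg <- sim_config(seed = 31, n_samples = 20, wgd_fraction = 0.55)
  sim <- simulate_genotypes(cfg)
  expect_identical(sim, simulate_genotypes(cfg))

  ## copy-number classes match the recorded truth, all five represented
  cls <- classify_cn(sim$allele_cn)
  expect_equal(cls$cn_class, sim$truth$cn_class_true)
  expect_setequal(unique(cls$cn_class), cn_classes())

  ## biallelic flags match the planted truth
  flags <- flag_biallelic(sim$allele_cn, sim$lesions,
                          metadata = sim$metadata)
  joined <- dplyr::left_join(sim$truth, flags, by = c("sample", "gene"))
  expect_equal(joined$biallelic_inactivation, joined$biallelic_true)

  ## WGD calls from the genome-wide segments match the planted truth
  wgd <- call_wgd(sim$segments, sim$metadata[c("sample", "ploidy")])
  jw <- dplyr::left_join(dplyr::distinct(sim$truth[c("sample", "wgd")]),
                         wgd, by = "sample", suffix = c("_true", ""))
  expect_equal(jw$wgd, jw$wgd_true)
})

test_that("simulated cohorts are written out as plain TSV files", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 41, n_samples = 4)
  sim <- simulate_telomere_tables(cfg)
  paths <- write_simdata(sim, dir)
  expect_setequal(basename(paths), c("ccircle.tsv", "qpcr.tsv", "truth.tsv"))
  back <- utils::read.delim(file.path(dir, "ccircle.tsv"))
  expect_equal(tibble::as_tibble(back), sim$ccircle, tolerance = 1e-12)
})
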