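# builds one clean record, then variants with planted rule violations
clean_snv <- function(n = 1) {
  tibble::tibble(
    chrom = "chr1", pos = seq_len(n) * 1000,
    variant_reads = 20, total_reads = 100,
    forward_variant_reads = 10, reverse_variant_reads = 10,
    control_coverage = 60, control_variant_bases = 0,
    error_profile = FALSE
  )
}

test_that("each SNV filter rule fires on its planted violation", {
  v <- clean_snv(9)
  v$variant_reads[2] <- 4; v$forward_variant_reads[2] <- 2
  v$reverse_variant_reads[2] <- 2; v$total_reads[2] <- 80  # rule 1, VAF 0.05
  v$variant_reads[3] <- 10; v$total_reads[3] <- 250
  v$forward_variant_reads[3] <- 5; v$reverse_variant_reads[3] <- 5  # rule 2
  v$forward_variant_reads[4] <- 20; v$reverse_variant_reads[4] <- 0
  v$error_profile[4] <- TRUE                             # rule 3
  v$control_coverage[5] <- 9                             # rule 4
  v$control_variant_bases[6] <- 2                        # rule 5: 2/60 = 1/30
  v$regions <- rep(list(character(0)), 9)
  v$regions[[7]] <- "blacklist"                          # rule 6
  v$regions[[8]] <- c("simple-repeat", "low-complexity") # rule 7
  v$control_coverage[9] <- NA                            # not determined

  res <- filter_snv(v)
  expect_true(res$pass[1])
  expect_equal(res$failed_rules[[2]], "min_variant_reads")
  expect_equal(res$failed_rules[[3]], "min_vaf")
  expect_equal(res$failed_rules[[4]], "strand_error_profile")
  expect_equal(res$failed_rules[[5]], "control_coverage")
  expect_equal(res$failed_rules[[6]], "control_variant_fraction")
  expect_equal(res$failed_rules[[7]], "mappability_blacklist")
  expect_equal(res$failed_rules[[8]], "repeat_overlap")
  expect_true(is.na(res$pass[9]))

  ## boundary behavior: thresholds are inclusive where specified
  b <- clean_snv(3)
  b$variant_reads <- c(5, 5, 5)
  b$total_reads <- c(100, 100, 101)   # VAF 0.05 passes, 0.0495 fails
  b$forward_variant_reads <- c(3, 3, 3); b$reverse_variant_reads <- c(2, 2, 2)
  b$control_coverage <- c(10, 60, 60)
  res_b <- filter_snv(b)
  expect_true(res_b$pass[1])
  expect_true(res_b$pass[2])
  expect_equal(res_b$failed_rules[[3]], "min_vaf")
})

test_that("a constructed cohort of planted violations is reproduced exactly", {
  set.seed(91)
  n <- 50
  rules <- snv_filter_rules()
  v <- clean_snv(n)
  v$regions <- rep(list(character(0)), n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    planted <- sample(rules, sample(0:3, 1))
    if ("min_variant_reads" %in% planted) {
      v$variant_reads[i] <- sample(0:4, 1)
      v$forward_variant_reads[i] <- v$variant_reads[i]
      v$reverse_variant_reads[i] <- 0
    }
    if ("min_vaf" %in% planted) {
      v$total_reads[i] <- max(v$variant_reads[i], 1) * 25  # VAF 0.04
    }
    if ("strand_error_profile" %in% planted) {
      v$reverse_variant_reads[i] <- 0
      v$forward_variant_reads[i] <- max(v$variant_reads[i], 1)
      v$variant_reads[i] <- max(v$variant_reads[i], 1)
      v$error_profile[i] <- TRUE
    }
    if ("control_coverage" %in% planted) v$control_coverage[i] <- sample(0:9, 1)
    if ("control_variant_fraction" %in% planted) {
      v$control_variant_bases[i] <- ceiling(v$control_coverage[i] / 30) + 1
    }
    if ("mappability_blacklist" %in% planted) {
      v$regions[[i]] <- c(v$regions[[i]], "low-mappability")
    }
    if ("repeat_overlap" %in% planted) {
      v$regions[[i]] <- c(v$regions[[i]], "tandem-repeat", "satellite")
    }
    ## side effects of the plants can trip additional rules; recompute the
    ## expected verdict from the rule definitions directly
    vaf <- v$variant_reads[i] / v$total_reads[i]
    expected <- c(
      if (v$variant_reads[i] < 5) "min_variant_reads",
      if (!(vaf >= 0.05)) "min_vaf",
      if ((v$forward_variant_reads[i] == 0 || v$reverse_variant_reads[i] == 0) &&
            v$variant_reads[i] > 0 && v$error_profile[i]) "strand_error_profile",
      if (v$control_coverage[i] < 10) "control_coverage",
      if (isTRUE(!(v$control_variant_bases[i] / v$control_coverage[i] < 1 / 30)))
        "control_variant_fraction",
      if (any(v$regions[[i]] %in% c("low-mappability", "blacklist")))
        "mappability_blacklist",
      if (sum(unique(v$regions[[i]]) %in%
                c("tandem-repeat", "simple-repeat", "low-complexity",
                  "satellite", "segmental-duplication")) >= 2) "repeat_overlap"
    )
    truth[[i]] <- rules[rules %in% expected]
  }
  res <- filter_snv(v)
  expect_identical(res$failed_rules, truth)
  expect_equal(res$pass, lengths(truth) == 0)
})

test_that("SNV filtering is idempotent and monotone in variant support", {
  set.seed(92)
  n <- 40
  v <- clean_snv(n)
  v$variant_reads <- sample(0:30, n, TRUE)
  v$total_reads <- v$variant_reads + sample(30:300, n, TRUE)
  v$forward_variant_reads <- floor(v$variant_reads / 2)
  v$reverse_variant_reads <- v$variant_reads - v$forward_variant_reads
  res <- filter_snv(v)
  passed <- res[which(res$pass), names(v)]
  again <- filter_snv(passed)
  expect_true(all(again$pass))

  ## raising variant support (keeping VAF structure) never flips rules 1-2
  boosted <- dplyr::mutate(v, variant_reads = variant_reads + 10,
                           total_reads = total_reads + 10,
                           forward_variant_reads = forward_variant_reads + 5,
                           reverse_variant_reads = reverse_variant_reads + 5)
  res_b <- filter_snv(boosted)
  for (i in seq_len(n)) {
    lost <- setdiff(res_b$failed_rules[[i]], res$failed_rules[[i]])
    expect_false(any(c("min_variant_reads") %in% lost))
  }
})

test_that("indel filtering follows the caller-flag rules", {
  ind <- tibble::tibble(
    filter = c("PASS", "alleleBias", "alleleBias", "badReads;strandBias",
               "PASS"),
    control_genotype = c("0/0", "0/0", "0/0", "0/0", "0/1"),
    vaf = c(0.5, 0.08, 0.25, 0.05, 0.4)
  )
  res <- filter_indel(ind)
  expect_true(res$pass[1])                      # PASS, somatic
  expect_false(res$pass[2])                     # flagged and VAF < 10%
  expect_equal(res$failed_rules[[2]], "flagged_low_vaf")
  expect_true(res$pass[3])                      # flagged but VAF >= 10%
  expect_false(res$pass[4])
  expect_false(res$pass[5])                     # germline
  expect_equal(res$failed_rules[[5]], "not_somatic")

  expect_warning(filter_indel(tibble::tibble(filter = "weirdFlag",
                                             control_genotype = "0/0",
                                             vaf = 0.05)),
                 "unrecognized")
})

test_that("region annotation uses 0-based half-open interval semantics", {
  vars <- tibble::tibble(chrom = "chr1", pos = c(100, 100, 250))
  sets <- list(
    blacklist = tibble::tibble(chrom = "chr1", start = 99, end = 100),
    "simple-repeat" = tibble::tibble(chrom = "chr1", start = 100, end = 200),
    "tandem-repeat" = tibble::tibble(chrom = "chr1", start = 240, end = 260),
    "satellite" = tibble::tibble(chrom = "chr1", start = 200, end = 300)
  )
  ann <- annotate_regions(vars, sets)
  expect_equal(ann$regions[[1]], "blacklist")   # pos 100 -> 0-based 99
  expect_equal(ann$regions[[2]], "blacklist")   # [100, 200) excludes 99
  expect_setequal(ann$regions[[3]], c("tandem-repeat", "satellite"))

  ## two repeat classes at once trip the repeat-overlap rule downstream
  snv <- clean_snv(1)
  snv$chrom <- "chr1"; snv$pos <- 250
  res <- filter_snv(annotate_regions(snv, sets))
  expect_equal(res$failed_rules[[1]], "repeat_overlap")

  expect_error(
    annotate_regions(vars, list(bad = tibble::tibble(chrom = "chr1",
                                                     start = 5, end = 2))),
    "malformed"
  )
})

test_that("error-profile contexts are matched by user-supplied patterns", {
  snvs <- tibble::tibble(context_seq = c("AAAGGCGGAAA", "ACGTACGTACG"))
  res <- flag_error_profiles(snvs, patterns = "GGCGG")
  expect_equal(res$error_profile, c(TRUE, FALSE))
  ## an empty pattern set disables the rule
  res0 <- flag_error_profiles(snvs)
  expect_false(any(res0$error_profile))
})
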