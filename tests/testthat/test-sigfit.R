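sigs3 <- random_signature_set(3, seed = 11)

test_that("NNLS recovers exact mixtures and handles degenerate input", {
  w <- sigs3$w
  f1 <- nnls_fit(100 * w[, 1], w)
  expect_equal(unname(f1$exposures), c(100, 0, 0), tolerance = 1e-8)
  expect_lt(f1$residual_norm, 1e-8)

  f0 <- nnls_fit(rep(0, 96), w)
  expect_equal(unname(f0$exposures), c(0, 0, 0))

  f2 <- nnls_fit(60 * w[, 1] + 40 * w[, 2], w)
  expect_equal(unname(f2$exposures), c(60, 40, 0), tolerance = 1e-8)
  expect_lt(f2$residual_norm, 1e-8)

  expect_error(nnls_fit(rep(1, 95), w), "dimension mismatch")
})

test_that("NNLS residual never increases when a signature is added", {
  set.seed(31)
  sigs6 <- random_signature_set(6, seed = 13)
  for (r in 1:20) {
    v <- rpois(96, lambda = runif(96, 0, 40))
    k <- sample(2:5, 1)
    sub <- sigs6$w[, 1:k, drop = FALSE]
    rss_small <- nnls_fit(v, sub)$rss
    rss_big <- nnls_fit(v, sigs6$w[, 1:(k + 1), drop = FALSE])$rss
    expect_lte(rss_big, rss_small + 1e-8)
  }
})

test_that("exposures scale linearly with the catalog", {
  set.seed(32)
  v <- rpois(96, lambda = 30)
  f1 <- nnls_fit(v, sigs3$w)
  f2 <- nnls_fit(7.5 * v, sigs3$w)
  expect_equal(f2$exposures, 7.5 * f1$exposures, tolerance = 1e-8)
})

test_that("two-pass decomposition drops sub-cutoff signatures and refits", {
  w <- sigs3$w
  ## with all cutoffs at zero an exact mixture behaves like one pass
  v <- 600 * w[, 1] + 400 * w[, 2]
  cat1 <- new_cat(v, "T1")
  fit0 <- supervised_decompose(cat1, sigs3, ci = FALSE)
  expect_equal(tidy(fit0)$exposure, c(600, 400, 0), tolerance = 1e-6)
  expect_equal(glance(fit0)$rss, glance(fit0)$rss_pass1, tolerance = 1e-12)

  ## a signature at relative exposure 0.05 is dropped by a 0.139839 cutoff
  sigs_cut <- signature_set(w, cutoffs = c(S1 = 0, S2 = 0.139839, S3 = 0))
  v2 <- 950 * w[, 1] + 50 * w[, 2]
  fit1 <- supervised_decompose(new_cat(v2, "T2"), sigs_cut, ci = FALSE)
  df <- tidy(fit1)
  expect_false(df$retained[df$signature == "S2"])
  expect_equal(df$exposure[df$signature == "S2"], 0)
  ## pass 2 equals an oracle NNLS restricted to the retained support
  ## (S3 sits at exactly zero in pass 1, so the strict cutoff drops it too);
  ## the restricted refit cannot beat the pass-1 residual
  kept <- df$signature[df$retained]
  oracle <- pracma::lsqnonneg(w[, kept, drop = FALSE], as.numeric(v2))
  expect_equal(df$exposure[df$signature %in% kept],
               as.numeric(oracle$x), tolerance = 1e-8)
  expect_gte(glance(fit1)$rss + 1e-9, glance(fit1)$rss_pass1)

  ## degenerate case: every signature under its cutoff
  sigs_hi <- signature_set(w, cutoffs = setNames(rep(0.99, 3), colnames(w)))
  fit2 <- supervised_decompose(new_cat(v2, "T3"), sigs_hi, ci = FALSE)
  expect_true(glance(fit2)$degenerate)
  expect_equal(tidy(fit2)$exposure, c(0, 0, 0))
  expect_equal(glance(fit2)$residual_norm, sqrt(sum(v2^2)))

  expect_error(supervised_decompose(new_cat(rep(0, 96), "T4"), sigs3),
               "non-positive total")
})

test_that("two-pass fits match the restricted-fit oracle on random mixtures", {
  set.seed(77)
  w <- random_signature_set(5, seed = 19)$w
  cutoffs <- setNames(runif(5, 0.02, 0.2), colnames(w))
  sigs <- signature_set(w, cutoffs)
  for (r in 1:100) {
    k <- sample(1:4, 1)
    support <- sample(5, k)
    h_true <- numeric(5)
    h_true[support] <- rmultinom(1, 1000, rep(1 / k, k))
    v <- as.numeric(w %*% h_true)
    fit <- supervised_decompose(new_cat(v, "S"), sigs, ci = FALSE)
    expos <- tidy(fit)$exposure
    ## oracle: pass 1 on the full set, threshold, restricted NNLS
    h1 <- pracma::lsqnonneg(w, v)$x
    keep <- (h1 / sum(v)) > cutoffs
    h_oracle <- numeric(5)
    if (any(keep)) {
      h_oracle[keep] <- pracma::lsqnonneg(w[, keep, drop = FALSE], v)$x
    }
    expect_equal(expos, h_oracle, tolerance = 1e-6)
  }
})

test_that("profile-likelihood machinery behaves at the point estimate", {
  w <- sigs3$w
  set.seed(41)
  v <- as.numeric(rmultinom(1, 3000, as.numeric(w %*% c(0.6, 0.3, 0.1))))
  fit <- nnls_fit(v, w)
  ## the unperturbed model tested against itself: LR = 0, p = 1
  sigma2 <- max(fit$rss / 96, 1e-9)
  lr0 <- (fit$rss - fit$rss) / sigma2
  expect_equal(pchisq(lr0, 1, lower.tail = FALSE), 1)

  ci <- exposure_ci(v, w, fit$exposures)
  expect_true(all(ci$ci_lo <= fit$exposures + 1e-6))
  expect_true(all(ci$ci_hi >= fit$exposures - 1e-6))
  expect_true(all(ci$ci_lo >= 0))
  ## at each finite limit the LR test p-value is alpha/2
  for (j in 1:3) {
    for (lim in c(ci$ci_lo[j], ci$ci_hi[j])) {
      if (lim <= 0 || !is.finite(lim)) next
      r <- v - lim * w[, j]
      sub <- pracma::lsqnonneg(w[, -j], r)
      rss_alt <- sum((r - w[, -j] %*% sub$x)^2)
      p <- pchisq((rss_alt - fit$rss) / sigma2, 1, lower.tail = FALSE)
      expect_equal(p, 0.025, tolerance = 1e-4)
    }
  }
})

test_that("securely detected signatures are those whose CI excludes zero", {
  w <- sigs3$w
  set.seed(43)
  v <- as.numeric(rmultinom(1, 4000, w %*% c(0.7, 0.3, 0)))
  fit <- supervised_decompose(new_cat(v, "T1"), sigs3)
  df <- tidy(fit)
  strong <- df$signature[df$sample == "T1" & df$retained & df$ci_lo > 0]
  for (s in strong) {
    expect_true(exposure_excludes_zero(fit, s)$excludes_zero)
  }
  dropped <- df$signature[!df$retained]
  for (s in dropped) {
    expect_false(exposure_excludes_zero(fit, s)$excludes_zero)
  }
  expect_error(exposure_excludes_zero(fit, "nope"), "unknown signature")
})

test_that("cohort enrichment matches exact hypergeometric computation", {
  ## identical proportions give p = 1
  res <- cohort_enrichment(
    tibble::tibble(signature = "S1", cohort_present = 10,
                   background_present = 10),
    cohort_n = 20, background_n = 20
  )
  expect_equal(res$p_value, 1)

  ## strongly unbalanced table vs brute-force tail summation
  res2 <- cohort_enrichment(
    tibble::tibble(signature = "S1", cohort_present = 8,
                   background_present = 2),
    cohort_n = 10, background_n = 10
  )
  expect_equal(res2$p_value, fisher_p_oracle(8, 2, 2, 8), tolerance = 1e-12)

  ## BH q-values are monotone in the rank of p and >= p
  set.seed(51)
  pres <- tibble::tibble(signature = paste0("S", 1:8),
                         cohort_present = sample(0:12, 8, TRUE),
                         background_present = sample(0:30, 8, TRUE))
  res3 <- cohort_enrichment(pres, cohort_n = 12, background_n = 30)
  expect_true(all(res3$q_value >= res3$p_value - 1e-12))
  o <- order(res3$p_value)
  expect_true(all(diff(res3$q_value[o]) >= -1e-12))
  expect_equal(res3$q_value, bh_oracle(res3$p_value))

  expect_error(cohort_enrichment(pres, cohort_n = 0, background_n = 30),
               "positive")
  expect_error(
    cohort_enrichment(tibble::tibble(signature = "S1", cohort_present = 30,
                                     background_present = 1),
                      cohort_n = 10, background_n = 10),
    "exceed"
  )
})
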