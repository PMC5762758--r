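#' Non-negative least squares fit of a mutational catalog column
#'
#' Solves `argmin_{h >= 0} || v - W h ||_2` by the Lawson-Hanson active-set
#' algorithm (via `pracma::lsqnonneg`). This is the elementary step of
#' supervised signature decomposition: `v` is one sample's 96-context
#' count vector and the columns of `W` are reference signatures.
#'
#' @param v Non-negative numeric vector (one catalog column).
#' @param w Signature matrix with `length(v)` rows, or a
#'   `"signature_set"` (its matrix is used).
#' @return Object of class `"nnls_fit"`: list with `exposures` (named,
#'   >= 0), `fitted`, `residuals` (`v - fitted`), `rss` and
#'   `residual_norm` (`sqrt(rss)`).
#' @export
#' @examples
#' sigs <- random_signature_set(3, seed = 1)
#' v <- 100 * sigs$w[, 1]
#' nnls_fit(v, sigs)$exposures
nnls_fit <- function(v, w) {
  if (inherits(w, "signature_set")) w <- w$w
  w <- as.matrix(w)
  v <- as.numeric(v)
  if (length(v) != nrow(w)) {
    abort(paste0("dimension mismatch: length(v) = ", length(v),
                 " but nrow(w) = ", nrow(w)))
  }
  if (any(v < 0)) abort("catalog vector must be non-negative")
  sol <- pracma::lsqnonneg(w, v)
  h <- setNames(as.numeric(sol$x), colnames(w))
  fitted <- as.numeric(w %*% h)
  res <- v - fitted
  structure(list(exposures = h, fitted = fitted, residuals = res,
                 rss = sum(res^2), residual_norm = sqrt(sum(res^2))),
            class = "nnls_fit")
}

#' @export
print.nnls_fit <- function(x, ...) {
  cat("<nnls_fit> residual norm", format(x$residual_norm), "\n")
  print(x$exposures)
  invisible(x)
}

#' @export
tidy.nnls_fit <- function(x, ...) {
  tibble(signature = names(x$exposures), exposure = unname(x$exposures))
}

#' Two-pass supervised signature decomposition
#'
#' Fits each catalog column against the full signature set by non-negative
#' least squares, drops every signature whose relative exposure (exposure
#' divided by the sample's total mutation count) does not exceed its
#' signature-specific cutoff, and refits with the retained signatures
#' only. The second pass increases specificity: weakly supported
#' signatures cannot absorb counts that belong to strongly supported
#' ones. Optionally, 95% profile-likelihood confidence intervals are
#' computed for every retained exposure ([exposure_ci()]).
#'
#' @param catalog Catalog tibble from [build_catalog()] (or any wide
#'   tibble with a `context` column and sample count columns). Columns
#'   must have positive totals.
#' @param sigs A `"signature_set"` (matrix + per-signature cutoffs).
#' @param ci Compute profile-likelihood confidence intervals
#'   (default `TRUE`).
#' @param alpha Two-sided CI level complement (default 0.05 for 95% CIs).
#' @return Object of class `"exposure_fit"` with elements `exposures`
#'   (tibble: `sample`, `signature`, `exposure`, `rel_exposure`, `ci_lo`,
#'   `ci_hi`, `retained`), `samples` (per-sample summaries) and
#'   `residuals` (named list of 96-vectors). CIs are on the absolute
#'   exposure scale (mutation counts); dropped signatures carry exposure
#'   exactly 0 and `NA` intervals.
#' @seealso [tidy.exposure_fit()], [glance.exposure_fit()],
#'   [autoplot.exposure_fit()]
#' @export
supervised_decompose <- function(catalog, sigs, ci = TRUE, alpha = 0.05) {
  stopifnot(inherits(sigs, "signature_set"))
  mat <- catalog_matrix(catalog)
  if (!setequal(rownames(mat), rownames(sigs$w))) {
    abort("catalog contexts do not match the signature matrix contexts")
  }
  mat <- mat[rownames(sigs$w), , drop = FALSE]
  if (any(mat < 0)) abort("catalog counts must be non-negative")
  totals <- colSums(mat)
  if (any(totals <= 0)) {
    abort(paste0("catalog column(s) with non-positive total: ",
                 paste(colnames(mat)[totals <= 0], collapse = ", ")))
  }

  w <- sigs$w
  cutoffs <- sigs$cutoffs
  per_sample <- purrr::map(colnames(mat), function(s) {
    v <- mat[, s]
    total <- sum(v)
    pass1 <- nnls_fit(v, w)
    keep <- (pass1$exposures / total) > cutoffs
    if (!any(keep)) {
      expo <- setNames(rep(0, ncol(w)), colnames(w))
      return(list(
        sample = s, exposures = expo, retained = keep,
        residuals = v, rss = sum(v^2), rss1 = pass1$rss,
        total = total, degenerate = TRUE,
        ci = tibble(signature = character(0), ci_lo = numeric(0),
                    ci_hi = numeric(0))
      ))
    }
    pass2 <- nnls_fit(v, w[, keep, drop = FALSE])
    expo <- setNames(rep(0, ncol(w)), colnames(w))
    expo[names(pass2$exposures)] <- pass2$exposures
    ci_tbl <- tibble(signature = names(pass2$exposures),
                     ci_lo = NA_real_, ci_hi = NA_real_)
    if (ci) {
      ci_tbl <- exposure_ci(v, w[, keep, drop = FALSE], pass2$exposures,
                            alpha = alpha)
    }
    list(sample = s, exposures = expo, retained = keep,
         residuals = pass2$residuals, rss = pass2$rss, rss1 = pass1$rss,
         total = total, degenerate = FALSE, ci = ci_tbl)
  })

  exposures <- purrr::map_dfr(per_sample, function(p) {
    out <- tibble(
      sample = p$sample,
      signature = colnames(w),
      exposure = unname(p$exposures),
      rel_exposure = unname(p$exposures) / p$total,
      retained = unname(p$retained)
    )
    dplyr::left_join(out, p$ci, by = "signature")
  })
  exposures <- exposures[, c("sample", "signature", "exposure",
                             "rel_exposure", "ci_lo", "ci_hi", "retained")]
  samples <- purrr::map_dfr(per_sample, function(p) {
    tibble(sample = p$sample, total_mutations = p$total,
           n_retained = sum(p$retained), rss = p$rss,
           residual_norm = sqrt(p$rss), rss_pass1 = p$rss1,
           degenerate = p$degenerate)
  })
  residuals <- setNames(purrr::map(per_sample, "residuals"),
                        purrr::map_chr(per_sample, "sample"))
  structure(list(exposures = exposures, samples = samples,
                 residuals = residuals, signatures = sigs, alpha = alpha,
                 ci_scale = "absolute exposure (mutation counts)"),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("<exposure_fit> ", nrow(x$samples), " sample(s), ",
      ncol(x$signatures$w), " candidate signature(s)\n", sep = "")
  print(x$samples)
  invisible(x)
}

#' Tidy an exposure fit into one row per sample-signature pair
#'
#' @param x An `"exposure_fit"`.
#' @param retained_only Keep only signatures retained after pass 2.
#' @param ... Unused.
#' @return Tibble with columns `sample`, `signature`, `exposure`,
#'   `rel_exposure`, `ci_lo`, `ci_hi`, `retained`.
#' @export
tidy.exposure_fit <- function(x, retained_only = FALSE, ...) {
  out <- x$exposures
  if (retained_only) out <- dplyr::filter(out, .data$retained)
  out
}

#' Per-sample summary of an exposure fit
#'
#' @param x An `"exposure_fit"`.
#' @param ... Unused.
#' @return Tibble with one row per sample: total mutations, number of
#'   retained signatures, residual sum of squares after each pass, and a
#'   degeneracy flag (all signatures dropped).
#' @export
glance.exposure_fit <- function(x, ...) {
  x$samples
}

#' Profile-likelihood confidence intervals for NNLS exposures
#'
#' For each retained signature the exposure is perturbed away from its
#' point estimate and held fixed while the remaining exposures are refit
#' by NNLS, giving an alternative model with one degree of freedom less.
#' Likelihoods treat the 96 residuals as i.i.d. Gaussian with variance
#' estimated from the unperturbed model's residuals (maximum-likelihood
#' estimate, floored at 1e-9 to avoid degeneracy on exact fits). The
#' likelihood-ratio statistic is referred to a 1-df chi-square, and each
#' CI limit is the perturbation where the test's p-value reaches
#' `alpha / 2` (0.025 per side for 95% intervals). Roots are located by
#' damped Newton steps on the residual-sum-of-squares profile (the
#' Gauss-Newton step for this one-parameter least-squares problem) with a
#' bisection fallback; the lower limit is floored at 0.
#'
#' @param v Non-negative 96-vector (one catalog column).
#' @param w Retained signature matrix (96 x k).
#' @param h Named exposure vector from the pass-2 fit on `v` and `w`.
#' @param alpha CI level complement (default 0.05).
#' @param tol Convergence tolerance on the p-value gap (default 1e-6).
#' @param max_iter Maximum root-finding iterations per limit (default 100).
#' @return Tibble with columns `signature`, `ci_lo`, `ci_hi`. A limit
#'   that fails to converge is reported as `-Inf`/`Inf` (unbounded on
#'   that side) with a warning.
#' @export
exposure_ci <- function(v, w, h, alpha = 0.05, tol = 1e-6, max_iter = 100) {
  if (inherits(w, "signature_set")) w <- w$w
  w <- as.matrix(w)
  v <- as.numeric(v)
  k <- ncol(w)
  stopifnot(length(h) == k)
  fitted <- as.numeric(w %*% h)
  rss0 <- sum((v - fitted)^2)
  n <- length(v)
  sigma2 <- max(rss0 / n, 1e-9)
  lr_crit <- qchisq(1 - alpha / 2, df = 1)
  p_target <- alpha / 2

  ## RSS of the alternative model with signature j fixed at exposure t
  profile_rss <- function(j, t) {
    r <- v - t * w[, j]
    if (k == 1) return(sum(r^2))
    sub <- pracma::lsqnonneg(w[, -j, drop = FALSE], r)
    resid <- r - as.numeric(w[, -j, drop = FALSE] %*% sub$x)
    sum(resid^2)
  }
  lr_stat <- function(j, t) (profile_rss(j, t) - rss0) / sigma2
  p_value <- function(j, t) pchisq(lr_stat(j, t), df = 1, lower.tail = FALSE)

  find_limit <- function(j, side) {
    hj <- h[j]
    ## bracket [a, b] with p(a) >= p_target >= p(b)
    if (side == "lower") {
      if (p_value(j, 0) >= p_target) return(0)
      a <- hj; b <- 0
    } else {
      step <- max(hj, sum(v) * 0.05, 1)
      b <- hj + step
      expand <- 0
      while (p_value(j, b) > p_target && expand < 60) {
        b <- hj + (b - hj) * 2
        expand <- expand + 1
      }
      if (p_value(j, b) > p_target) {
        warn(paste0("upper CI limit for '", names(h)[j],
                    "' did not converge; reported as Inf"))
        return(Inf)
      }
      a <- hj
    }
    t <- (a + b) / 2
    for (iter in seq_len(max_iter)) {
      pv <- p_value(j, t)
      if (abs(pv - p_target) < tol) return(max(t, 0))
      if (pv > p_target) a <- t else b <- t
      ## Newton step on g(t) = LR(t) - crit, with numerical derivative
      g <- lr_stat(j, t) - lr_crit
      dd <- max(abs(b - a) * 1e-3, 1e-8)
      dg <- (lr_stat(j, t + dd) - lr_stat(j, t - dd)) / (2 * dd)
      t_new <- if (is.finite(dg) && abs(dg) > 1e-12) t - g / dg else NA_real_
      inside <- !is.na(t_new) && t_new > min(a, b) && t_new < max(a, b)
      t <- if (inside) t_new else (a + b) / 2
    }
    pv <- p_value(j, t)
    if (abs(pv - p_target) < 1e-3) return(max(t, 0))
    warn(paste0(side, " CI limit for '", names(h)[j],
                "' did not converge; reported as unbounded"))
    if (side == "lower") -Inf else Inf
  }

  tibble(
    signature = names(h),
    ci_lo = vapply(seq_len(k), find_limit, numeric(1), side = "lower"),
    ci_hi = vapply(seq_len(k), find_limit, numeric(1), side = "upper")
  )
}

#' Does a signature's confidence interval exclude zero?
#'
#' A retained signature's exposure is considered securely detected in a
#' sample when the lower 95% profile-likelihood limit is strictly
#' positive. Signatures dropped during the two-pass fit have exposure 0
#' and always return `FALSE`.
#'
#' @param fit An `"exposure_fit"` with CIs computed.
#' @param signature Signature id.
#' @return Tibble with columns `sample` and `excludes_zero` (logical).
#' @export
exposure_excludes_zero <- function(fit, signature) {
  stopifnot(inherits(fit, "exposure_fit"))
  df <- dplyr::filter(fit$exposures, .data$signature == !!signature)
  if (nrow(df) == 0) abort(paste0("unknown signature '", signature, "'"))
  tibble(sample = df$sample,
         excludes_zero = df$retained & !is.na(df$ci_lo) & df$ci_lo > 0)
}

#' Cohort-level signature enrichment against a background corpus
#'
#' For each signature, compares the number of cohort samples in which the
#' signature is present with the number of background samples in which it
#' is present, by a two-sided Fisher exact test on the 2x2 presence/
#' absence table, with Benjamini-Hochberg correction across signatures.
#' "Presence" means retained after the second NNLS pass with positive
#' exposure (an optional stricter definition requires the CI to exclude
#' zero; the caller supplies counts, so either is supported).
#'
#' @param presence Tibble with columns `signature`, `cohort_present`,
#'   `background_present` (sample counts).
#' @param cohort_n,background_n Cohort and background sizes.
#' @return Tibble with columns `signature`, `cohort_present`,
#'   `cohort_absent`, `background_present`, `background_absent`,
#'   `odds_ratio`, `p_value`, `q_value` (BH-adjusted).
#' @export
cohort_enrichment <- function(presence, cohort_n, background_n) {
  presence <- as_tibble(presence)
  stopifnot(all(c("signature", "cohort_present", "background_present") %in%
                  names(presence)))
  if (cohort_n <= 0) abort("cohort size must be positive")
  if (background_n <= 0) abort("background size must be positive")
  if (any(presence$cohort_present > cohort_n) ||
      any(presence$background_present > background_n)) {
    abort("presence counts cannot exceed the corresponding cohort size")
  }
  res <- purrr::pmap_dfr(
    list(presence$signature, presence$cohort_present,
         presence$background_present),
    function(sig, cp, bp) {
      tab <- matrix(c(cp, cohort_n - cp, bp, background_n - bp), nrow = 2)
      ft <- fisher.test(tab, alternative = "two.sided")
      tibble(signature = sig, cohort_present = cp,
             cohort_absent = cohort_n - cp, background_present = bp,
             background_absent = background_n - bp,
             odds_ratio = unname(ft$estimate), p_value = ft$p.value)
    }
  )
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res
}
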