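#' Construct a signature set
#'
#' A signature set bundles a reference signature matrix (96 contexts x S
#' signatures, each column a probability distribution over the contexts)
#' with a per-signature relative-exposure cutoff used by the two-pass
#' supervised decomposition ([supervised_decompose()]).
#'
#' @param w Numeric matrix, 96 x S, non-negative, columns summing to 1
#'   (within 1e-6). Row names must be the 96 context labels
#'   ([sbs_contexts()]); column names are signature ids.
#' @param cutoffs Named numeric vector of relative-exposure cutoffs in
#'   `[0, 1)`, one per signature. Default 0 for every signature (any
#'   positive first-pass exposure is retained).
#' @return An object of class `"signature_set"`.
#' @export
signature_set <- function(w, cutoffs = NULL) {
  w <- as.matrix(w)
  if (nrow(w) != 96) abort("signature matrix must have 96 rows")
  if (is.null(rownames(w))) {
    rownames(w) <- sbs_contexts()
  } else if (!setequal(rownames(w), sbs_contexts())) {
    abort("signature matrix row names must be the 96 context labels")
  } else {
    w <- w[sbs_contexts(), , drop = FALSE]
  }
  if (is.null(colnames(w))) colnames(w) <- paste0("S", seq_len(ncol(w)))
  if (any(w < 0)) abort("signature matrix must be non-negative")
  csum <- colSums(w)
  if (any(abs(csum - 1) > 1e-6)) {
    abort("signature matrix columns must sum to 1 (within 1e-6)")
  }
  if (is.null(cutoffs)) {
    cutoffs <- setNames(rep(0, ncol(w)), colnames(w))
  }
  if (is.null(names(cutoffs)) || !all(colnames(w) %in% names(cutoffs))) {
    abort("`cutoffs` must be named and cover every signature")
  }
  cutoffs <- cutoffs[colnames(w)]
  if (any(cutoffs < 0 | cutoffs >= 1)) abort("cutoffs must lie in [0, 1)")
  structure(list(w = w, cutoffs = cutoffs), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("<signature_set> ", ncol(x$w), " signatures x 96 contexts\n", sep = "")
  cat("signatures:", paste(colnames(x$w), collapse = ", "), "\n")
  invisible(x)
}

#' Published relative-exposure cutoffs for the 30 COSMIC signatures
#'
#' Signature-specific thresholds on the relative exposure (fraction of a
#' sample's mutations) below which a signature is dropped between the two
#' NNLS passes. They were derived by ROC analysis on a 7042-sample
#' pan-cancer corpus and are used here as fixed constants; a cutoff of 0
#' (e.g. AC1, AC5) retains any signature with positive first-pass exposure.
#'
#' @return Tibble with columns `signature` (`"AC1"`..`"AC30"`) and `cutoff`.
#' @export
cosmic_cutoffs <- function() {
  tibble(
    signature = paste0("AC", 1:30),
    cutoff = c(0, 0.03404847, 0.139839, 0.02281439, 0, 0.003660315,
               0.02841319, 0.1870989, 0.0953648, 0.0164065, 0.08238725,
               0.1920715, 0.03769936, 0.03080224, 0.03182855, 0.3553548,
               0.004075963, 0.2692715, 0.04038686, 0.05066134, 0.04219805,
               0.03908793, 0.03900049, 0.04254174, 0.02448377, 0.02830282,
               0.02223076, 0.0315642, 0.07392201, 0.06332517)
  )
}

#' Generate a random synthetic signature set
#'
#' Draws each signature column from a symmetric Dirichlet distribution
#' over the 96 contexts. The default concentration (`alpha = 0.5`) gives
#' signatures with a Shannon entropy around 3.8 nats (of a possible
#' ln 96 = 4.56), matching the mid-range sharpness of real reference
#' signatures, which span roughly 2 nats (highly focused, e.g. UV- or
#' APOBEC-type) to 4.4 nats (near-flat); smaller `alpha` gives sparser,
#' more focused signatures.
#'
#' @param n_signatures Number of signatures.
#' @param seed Integer seed (fixed seed gives a bit-identical set).
#' @param alpha Dirichlet concentration (default 0.5; smaller = sparser).
#' @param cutoffs Optional named cutoff vector; default all 0.
#' @return A `"signature_set"` with signatures named `"S1"`, `"S2"`, ...
#' @export
random_signature_set <- function(n_signatures, seed = 1, alpha = 0.5,
                                 cutoffs = NULL) {
  w <- withr::with_seed(seed, {
    m <- matrix(rgamma(96 * n_signatures, shape = alpha), nrow = 96)
    sweep(m, 2, colSums(m), "/")
  })
  rownames(w) <- sbs_contexts()
  colnames(w) <- paste0("S", seq_len(n_signatures))
  signature_set(w, cutoffs)
}

#' Read a signature matrix (and optional cutoffs) from TSV
#'
#' The matrix file must have a first column of 96 context labels matching
#' [sbs_contexts()] and one numeric column per signature. The cutoff file,
#' if given, has columns `signature` and `cutoff`.
#'
#' @param path Path to the signature matrix TSV.
#' @param cutoff_path Optional path to a cutoffs TSV.
#' @return A `"signature_set"`.
#' @export
read_signature_matrix <- function(path, cutoff_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  w <- as.matrix(df[, -1, drop = FALSE])
  rownames(w) <- df[[1]]
  cutoffs <- NULL
  if (!is.null(cutoff_path)) {
    cf <- utils::read.delim(cutoff_path, stringsAsFactors = FALSE)
    cutoffs <- setNames(cf$cutoff, cf$signature)
  }
  signature_set(w, cutoffs)
}

#' Write a catalog or signature matrix to TSV
#'
#' @param x A catalog tibble or `"signature_set"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(x, path) {
  if (inherits(x, "signature_set")) {
    x <- cbind(data.frame(context = rownames(x$w)), as.data.frame(x$w))
  }
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a catalog TSV
#'
#' @param path Path to a catalog TSV written by [write_catalog()] (first
#'   column `context`, one column per sample).
#' @return A catalog tibble.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  if (!setequal(rownames(mat), sbs_contexts())) {
    abort("catalog file does not contain the 96 context labels")
  }
  new_catalog(mat[sbs_contexts(), , drop = FALSE])
}
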