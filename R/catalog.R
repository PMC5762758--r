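#' Build per-sample 96-context mutational catalogs from somatic SNVs
#'
#' Each SNV is classified into one of the 96 trinucleotide substitution
#' classes ([sbs_contexts()]). Records whose reference base is a purine are
#' reverse-complemented onto the pyrimidine strand before classification,
#' so a `G>A` change in context `TGT` counts as `A[C>T]A`.
#'
#' @param snvs A data frame with columns `sample`, `ref`, `alt` and
#'   `context` (the reference-strand 3-mer centered on the variant
#'   position). `chrom`/`pos` columns may be present but are not used.
#' @return A wide tibble with a `context` column holding the 96 class
#'   labels in canonical order and one non-negative count column per
#'   sample (samples in alphabetical order). Class `"mutational_catalog"`.
#' @details Records containing `N` in the context are dropped with a
#'   warning (their tally is reported). Records whose context middle base
#'   disagrees with `ref`, or with `ref == alt`, or with non-ACGT bases,
#'   raise a validation error listing the offending rows.
#' @export
#' @examples
#' snvs <- tibble::tibble(sample = "S1", ref = "C", alt = "T", context = "ACA")
#' cat96 <- build_catalog(snvs)
#' cat96[cat96$S1 > 0, ]
build_catalog <- function(snvs) {
  snvs <- as_tibble(snvs)
  required <- c("sample", "ref", "alt", "context")
  missing_cols <- setdiff(required, names(snvs))
  if (length(missing_cols) > 0) {
    abort(paste0("`snvs` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  contexts <- sbs_contexts()
  samples <- sort(unique(as.character(snvs$sample)))
  empty <- matrix(0, nrow = 96, ncol = length(samples),
                  dimnames = list(contexts, samples))
  if (nrow(snvs) == 0) {
    return(new_catalog(empty))
  }

  ref <- toupper(snvs$ref)
  alt <- toupper(snvs$alt)
  ctx <- toupper(snvs$context)

  has_n <- grepl("N", ctx, fixed = TRUE)
  if (any(has_n)) {
    warn(paste0(sum(has_n), " record(s) with N-containing contexts were ",
                "excluded from the catalog"))
    snvs <- snvs[!has_n, , drop = FALSE]
    ref <- ref[!has_n]; alt <- alt[!has_n]; ctx <- ctx[!has_n]
    if (nrow(snvs) == 0) return(new_catalog(empty))
  }

  bad <- !(ref %in% c("A", "C", "G", "T")) |
    !(alt %in% c("A", "C", "G", "T")) |
    nchar(ctx) != 3 |
    substr(ctx, 2, 2) != ref |
    ref == alt
  if (any(bad)) {
    abort(paste0("invalid SNV record(s) at row(s): ",
                 paste(which(bad), collapse = ", "),
                 " (require single A/C/G/T ref != alt and a 3-base context ",
                 "whose middle base equals ref)"))
  }

  ## fold purine-reference records onto the pyrimidine strand
  purine <- ref %in% c("A", "G")
  ctx[purine] <- revcomp(ctx[purine])
  alt[purine] <- complement_base(alt[purine])

  label <- context_label(ctx, alt)
  counts <- table(factor(label, levels = contexts),
                  factor(as.character(snvs$sample), levels = samples))
  mat <- empty
  mat[rownames(counts), colnames(counts)] <- as.matrix(counts)
  new_catalog(mat)
}

new_catalog <- function(mat) {
  out <- tibble(context = rownames(mat))
  for (s in colnames(mat)) out[[s]] <- unname(mat[, s])
  class(out) <- c("mutational_catalog", class(out))
  out
}

#' Extract the count matrix from a catalog tibble
#'
#' @param catalog A catalog as returned by [build_catalog()] (wide tibble
#'   with a `context` column and one column per sample).
#' @return Numeric matrix, 96 contexts x samples, with context row names.
#' @export
catalog_matrix <- function(catalog) {
  stopifnot("context" %in% names(catalog))
  samples <- setdiff(names(catalog), "context")
  mat <- as.matrix(catalog[samples])
  if (!is.numeric(mat)) mode(mat) <- "numeric"
  rownames(mat) <- catalog$context
  mat
}

#' Count pyrimidine-centered trinucleotides in a region set
#'
#' Counts every 3-mer whose center base lies inside one of the supplied
#' intervals, folding purine-centered 3-mers onto the pyrimidine strand.
#' Overlapping or duplicate intervals are merged first so no position is
#' counted twice. N-containing 3-mers are skipped (a tally is reported).
#'
#' @param regions Data frame with columns `chrom`, `start`, `end` giving
#'   0-based half-open intervals (BED convention).
#' @param reference Named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @return Tibble with columns `triplet` (the 32 pyrimidine-centered
#'   3-mers) and `count`.
#' @export
#' @examples
#' count_triplets(tibble::tibble(chrom = "c1", start = 1, end = 2),
#'                c(c1 = "AACAA"))
count_triplets <- function(regions, reference) {
  regions <- as_tibble(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (inherits(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  reference <- toupper(reference)

  counts <- setNames(numeric(32), pyrimidine_triplets())
  n_skipped <- 0L
  for (chrom in unique(as.character(regions$chrom))) {
    if (!chrom %in% names(reference)) {
      abort(paste0("chromosome '", chrom, "' not found in the reference"))
    }
    seq <- reference[[chrom]]
    len <- nchar(seq)
    sub <- regions[regions$chrom == chrom, ]
    if (any(sub$end > len)) {
      i <- which(sub$end > len)[1]
      abort(paste0("interval ", chrom, ":", sub$start[i], "-", sub$end[i],
                   " extends beyond the contig end (length ", len, ")"))
    }
    merged <- merge_intervals(sub$start, sub$end)
    for (k in seq_len(nrow(merged))) {
      s <- merged$start[k]; e <- merged$end[k]
      ## 1-based window whose internal 3-mers have centers in [s, e)
      w1 <- max(s, 1)
      w2 <- min(e + 1, len)
      if (w2 - w1 < 2) next
      win <- substr(seq, w1, w2)
      n <- nchar(win)
      tri <- substring(win, 1:(n - 2), 3:n)
      keep <- !grepl("N", tri, fixed = TRUE)
      n_skipped <- n_skipped + sum(!keep)
      tri <- fold_triplet(tri[keep])
      tab <- table(tri)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  if (n_skipped > 0) {
    warn(paste0(n_skipped, " N-containing 3-mer(s) skipped during counting"))
  }
  tibble(triplet = names(counts), count = unname(counts))
}

## merge 0-based half-open intervals; uses IRanges when available
merge_intervals <- function(start, end) {
  if (any(end < start)) abort("interval with end < start")
  if (requireNamespace("IRanges", quietly = TRUE)) {
    ir <- IRanges::reduce(IRanges::IRanges(start = start + 1, end = end))
    return(tibble(start = IRanges::start(ir) - 1, end = IRanges::end(ir)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble(start = c(out_s, ms), end = c(out_e, me))
}

#' Correct a catalog for triplet-motif composition differences
#'
#' Exome capture regions do not contain trinucleotide motifs in the same
#' proportions as the whole genome, which biases exposures fitted against
#' genome-derived signatures. Each of the 96 context rows is rescaled by
#' the ratio of the genome-wide relative frequency of its underlying
#' 3-mer to the relative frequency in the capture target, so the corrected
#' catalog approximates what whole-genome sequencing would have observed.
#'
#' @param catalog Catalog tibble from [build_catalog()].
#' @param target,genome Triplet frequency tibbles from [count_triplets()]
#'   (columns `triplet`, `count`) for the capture target and the whole
#'   genome respectively. All 32 target frequencies must be positive.
#' @return A catalog tibble with rescaled (possibly non-integer) counts.
#' @export
normalize_motifs <- function(catalog, target, genome) {
  ratio <- motif_ratio(target, genome)
  mat <- catalog_matrix(catalog)
  tri <- context_to_triplet(rownames(mat))
  mat <- mat * ratio[tri]
  new_catalog(mat)
}

#' Undo a triplet-motif correction
#'
#' Inverse of [normalize_motifs()]: divides each context row by the
#' genome/target relative-frequency ratio.
#'
#' @inheritParams normalize_motifs
#' @return A catalog tibble.
#' @export
denormalize_motifs <- function(catalog, target, genome) {
  ratio <- motif_ratio(target, genome)
  mat <- catalog_matrix(catalog)
  tri <- context_to_triplet(rownames(mat))
  mat <- mat / ratio[tri]
  new_catalog(mat)
}

motif_ratio <- function(target, genome) {
  target <- as_tibble(target); genome <- as_tibble(genome)
  stopifnot(all(c("triplet", "count") %in% names(target)),
            all(c("triplet", "count") %in% names(genome)))
  t_counts <- setNames(target$count, target$triplet)
  g_counts <- setNames(genome$count, genome$triplet)
  trip <- pyrimidine_triplets()
  if (!all(trip %in% names(t_counts)) || !all(trip %in% names(g_counts))) {
    abort("target and genome frequencies must cover all 32 pyrimidine-centered 3-mers")
  }
  if (any(t_counts[trip] <= 0)) {
    abort("zero target triplet frequency: motif correction undefined")
  }
  t_rel <- t_counts[trip] / sum(t_counts[trip])
  g_rel <- g_counts[trip] / sum(g_counts[trip])
  g_rel / t_rel
}

#' Attach trinucleotide contexts to SNV records from a reference
#'
#' Looks up the 3-mer centered on each variant position (1-based, VCF
#' convention): bases `pos - 1 .. pos + 1` on the reference strand.
#'
#' @param snvs Data frame with columns `chrom`, `pos`, `ref`.
#' @param reference Named character vector of chromosome sequences or a
#'   `Biostrings::DNAStringSet` (e.g. from `Biostrings::readDNAStringSet`).
#' @return `snvs` with a `context` column added.
#' @export
add_context <- function(snvs, reference) {
  snvs <- as_tibble(snvs)
  stopifnot(all(c("chrom", "pos", "ref") %in% names(snvs)))
  if (inherits(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  reference <- toupper(reference)
  chrom <- as.character(snvs$chrom)
  bad_chrom <- setdiff(unique(chrom), names(reference))
  if (length(bad_chrom) > 0) {
    abort(paste0("chromosome(s) not in reference: ",
                 paste(bad_chrom, collapse = ", ")))
  }
  lens <- nchar(reference)[chrom]
  if (any(snvs$pos < 2 | snvs$pos > lens - 1)) {
    abort("variant position too close to a contig end for a 3-mer context")
  }
  ctx <- substr(reference[chrom], snvs$pos - 1, snvs$pos + 1)
  mid <- substr(ctx, 2, 2)
  if (any(mid != toupper(snvs$ref))) {
    abort(paste0("reference base mismatch at row(s): ",
                 paste(which(mid != toupper(snvs$ref)), collapse = ", ")))
  }
  snvs$context <- unname(ctx)
  snvs
}
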