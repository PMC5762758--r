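#' Read a SEG-like segment table
#'
#' @param path TSV with columns `sample`, `chrom`, `start`, `end` and
#'   `log2` and/or `state`.
#' @return A validated segment tibble.
#' @export
read_seg <- function(path) {
  validate_segments(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read biallelic SNVs from a VCF file
#'
#' Thin wrapper over `vcfR` that extracts chromosome, position, ref and
#' alt for single-nucleotide, biallelic records. Multi-allelic or
#' non-SNV records are rejected with an error (split them upstream).
#'
#' @param path Path to a VCF file.
#' @param sample Sample id to attach to every record (default: the file
#'   base name).
#' @return Tibble with columns `sample`, `chrom`, `pos`, `ref`, `alt`.
#' @export
read_vcf_snvs <- function(path, sample = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    abort("multi-allelic records found; split them upstream")
  }
  if (any(nchar(fix$REF) != 1 | nchar(fix$ALT) != 1)) {
    abort("non-SNV records found; this reader accepts single-base ref/alt only")
  }
  tibble(sample = sample %||% sub("\\.vcf(\\.gz)?$", "", basename(path)),
         chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
         alt = fix$ALT)
}

#' Read a FASTA reference into a named character vector
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of sequences, names truncated at the
#'   first whitespace.
#' @export
read_reference <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the 'Biostrings' package")
  }
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  setNames(as.character(x), names(x))
}
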