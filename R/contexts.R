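#' The 96 trinucleotide substitution contexts
#'
#' Somatic single-base substitutions are conventionally reported on the
#' pyrimidine strand: every mutation is expressed as a change of a C or T,
#' flanked by one base on each side, giving 6 substitution types x 4 x 4
#' flanking bases = 96 classes. Labels follow the COSMIC convention,
#' e.g. `"A[C>A]A"`, ordered by substitution type (C>A, C>G, C>T, T>A,
#' T>C, T>G), then 5' flank, then 3' flank.
#'
#' @return Character vector of length 96 with the canonical class labels.
#' @export
#' @examples
#' head(sbs_contexts())
sbs_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(f5, f3) {
      paste0(f5, "[", s, "]", f3)
    })))
  }))
}

#' The 32 pyrimidine-centered trinucleotides
#'
#' All 3-mers whose middle base is C or T, in lexicographic order. Purine-
#' centered 3-mers are folded onto this set by reverse complementation.
#'
#' @return Character vector of length 32.
#' @export
pyrimidine_triplets <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(f3 = bases, mid = c("C", "T"), f5 = bases,
                      stringsAsFactors = FALSE)
  sort(paste0(grid$f5, grid$mid, grid$f3))
}

complement_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of the reverse complements.
#' @export
#' @examples
#' revcomp("TGT") # "ACA"
revcomp <- function(x) {
  vapply(strsplit(complement_base(x), ""), function(b) {
    paste(rev(b), collapse = "")
  }, character(1))
}

#' Fold trinucleotides onto the pyrimidine strand
#'
#' 3-mers centered on a purine (A or G) are replaced by their reverse
#' complement so that every triplet is centered on C or T.
#'
#' @param triplet Character vector of 3-mers.
#' @return Character vector of pyrimidine-centered 3-mers.
#' @export
fold_triplet <- function(triplet) {
  mid <- substr(triplet, 2, 2)
  purine <- mid %in% c("A", "G")
  out <- triplet
  out[purine] <- revcomp(triplet[purine])
  out
}

## context label for pyrimidine-strand ref/alt and 3-mer context
context_label <- function(context, alt) {
  paste0(substr(context, 1, 1), "[", substr(context, 2, 2), ">", alt, "]",
         substr(context, 3, 3))
}

## triplet underlying a 96-class label: "A[C>T]G" -> "ACG"
context_to_triplet <- function(label) {
  paste0(substr(label, 1, 1), substr(label, 3, 3), substr(label, 7, 7))
}
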