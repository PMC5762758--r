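# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration and direct formulas.

## two-sided Fisher exact p by exhaustive hypergeometric tail summation
## over all tables with the same margins (R's convention: sum of point
## probabilities <= that of the observed table, with a small relative slack)
fisher_p_oracle <- function(a, b, c, d) {
  m1 <- a + b           # row 1 total
  n1 <- a + c           # col 1 total
  n2 <- b + d           # col 2 total
  lo <- max(0, m1 - n2)
  hi <- min(m1, n1)
  x <- lo:hi
  probs <- stats::dhyper(x, n1, n2, m1)
  p_obs <- stats::dhyper(a, n1, n2, m1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Benjamini-Hochberg q-values by the direct sort-based definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

## exhaustive chromothripsis switch oracle: enumerate every contiguous
## window of segments, keep those that alternate between exactly two
## states, and return the max switch count with its (smallest) span
switch_oracle <- function(states, start, end) {
  n <- length(states)
  bp <- function(i) (end[i] + start[i + 1]) / 2
  best_sw <- 0
  best_span <- 0
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        w <- states[i:j]
        changes <- all(w[-1] != w[-length(w)])
        two_state <- length(unique(w)) <= 2
        if (changes && two_state) {
          sw <- j - i
          span <- if (sw < 2) 0 else (bp(j - 1) - bp(i)) / 1e6
          if (sw > best_sw || (sw == best_sw && span < best_span)) {
            best_sw <- sw
            best_span <- span
          }
        }
      }
    }
  }
  list(n_switches = best_sw, span_mb = best_span)
}

## independently coded copy-number genotype truth table
cn_class_oracle <- function(major, minor) {
  if (major == 0 && minor == 0) return("homozygous_deletion")
  if (minor > 0) return("normal_biallelic")
  if (major == 1) return("LOH")
  if (major == 2) return("CNN_LOH")
  "higher_ploidy_LOH"
}

## one-sample catalog tibble from a raw 96-vector
new_cat <- function(v, sample) {
  out <- tibble::tibble(context = sbs_contexts())
  out[[sample]] <- as.numeric(v)
  out
}

## segment builder: k alternating 2/1 switches, breakpoint midpoints
## exactly span_mb apart between the first and last switch
alternating_profile <- function(k, span_mb, sample = "S", chrom = "chr1",
                                offset = 10e6, chrom_len = 250e6) {
  stopifnot(k >= 1)
  if (k == 1) {
    bp <- offset
  } else {
    bp <- round(offset + (seq_len(k) - 1) * span_mb * 1e6 / (k - 1))
    bp[k] <- offset + span_mb * 1e6
  }
  bounds <- c(0, bp, chrom_len)
  tibble::tibble(
    sample = sample, chrom = chrom,
    start = bounds[-length(bounds)] + 1, end = bounds[-1],
    state = rep(c(2, 1), length.out = k + 1)
  )
}
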