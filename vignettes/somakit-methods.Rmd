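---
title: "Methods and modeling choices in somakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling choices in somakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somakit)
library(dplyr)
```

somakit implements the bespoke computational stages of an integrative
somatic-genome characterization workflow for tumor cohorts: mutational
catalogs and supervised signature decomposition, chromothripsis calling
from segmented copy-number profiles, ALT (alternative lengthening of
telomeres) classification, genotype/biallelic-inactivation integration,
and heuristic variant filtering. This vignette records the statistical
model behind each stage, every non-obvious parameter default, and the
numerical choices, so that results are interpretable without reading the
source.

## Mutational catalogs

A catalog is the per-sample count vector over the 96 trinucleotide
substitution classes: six pyrimidine-centered substitutions (C>A, C>G,
C>T, T>A, T>C, T>G) in each of the 16 flanking-base combinations.
Purine-centered calls are folded onto the pyrimidine strand by reverse
complement, the universal convention that makes catalogs strand-agnostic.

```{r, eval = FALSE}
snvs <- tibble::tibble(sample = "S1", ref = "G", alt = "A",
                       context = "TGT")   # folds to A[C>T]A
cat <- build_catalog(snvs)
```

Catalogs from targeted sequencing are corrected for motif availability
with `normalize_motifs()`: each context row is scaled by the ratio of the
*relative* genome-wide frequency of its 3-mer to its relative frequency
in the capture target. Relative frequencies make the correction invariant
to the sizes of the two region sets; a zero target frequency leaves the
correction undefined and is an error rather than a silent `Inf`.

## Supervised signature decomposition

Each sample's catalog `v` is modeled as `v ≈ W h` with `W` the fixed
96 × K signature matrix (columns sum to 1) and `h ≥ 0` the exposures.
`h` is estimated by non-negative least squares (NNLS, via
`pracma::lsqnonneg`). The decomposition is *supervised* and two-pass:

1. fit all K signatures;
2. drop every signature whose relative exposure (exposure divided by the
   sample's total mutation count) is **not strictly greater** than its
   signature-specific cutoff;
3. refit on the retained set only.

The strict inequality means a cutoff of zero still removes signatures
whose pass-1 exposure is exactly zero, so the retained set is always the
support actually used. Published per-signature cutoffs for the 30-
signature reference set are shipped as `cosmic_cutoffs()`; they encode
how easily each signature absorbs noise from flat profiles.

### Confidence intervals

`supervised_decompose(ci = TRUE)` attaches 95% profile-likelihood
intervals to each retained exposure. The residuals are treated as i.i.d.
Gaussian with variance estimated from the fit itself,
`sigma2 = RSS / 96`, floored at `1e-9` so that numerically perfect fits
do not produce a zero variance and infinite likelihood-ratio statistics.
For a candidate value `t` of one exposure, its contribution `t * w_j` is
subtracted from `v`, the remaining exposures are refit by NNLS, and the
likelihood-ratio statistic `(RSS(t) - RSS0) / sigma2` is referred to a
1-df chi-square. Each limit is the value of `t` where the tail
probability equals `alpha / 2` (so 0.025 per side at `alpha = 0.05`),
found by bracketing followed by damped Newton steps with a bisection
fallback, to a tolerance of `1e-6` on the tail probability and at most
100 iterations; non-convergence yields an infinite limit with a warning
rather than a fabricated number. Lower limits are floored at zero, the
boundary of the parameter space.

### Known limitation: anti-conservative coverage under count noise

The Gaussian working likelihood is homoscedastic, but multinomial count
noise is not: variance scales with the expected count per context.
Calibration on simulated cohorts (200 samples, 5,000 mutations each,
three-signature mixture, multinomial noise) measures empirical coverage
of the nominal 95% intervals at **90.8%**, i.e. the intervals are
somewhat too short. Diagnostics attribute this fully to the variance
model: under correctly specified i.i.d. Gaussian noise the same code
covers at 95.7%, while delta-method standard errors under multinomial
noise exceed the homoscedastic ones by 30–50% for sharply peaked
signatures. Coverage improves as signatures flatten (the per-context
variance becomes more uniform). Treat the intervals as mildly
anti-conservative for sparse, peaked signatures; the point estimates are
unaffected.

### Cohort enrichment

`cohort_enrichment()` compares per-signature presence counts between a
cohort and a background corpus with a two-sided Fisher exact test and
Benjamini–Hochberg correction across signatures. Both steps delegate to
`stats::fisher.test()` and `stats::p.adjust()`; the test suite verifies
them against an independent exhaustive hypergeometric enumeration and a
direct sort-based BH implementation on every 2 × 2 table with margins up
to 12.

## Chromothripsis

The caller operationalizes the oscillating copy-number pattern of
chromothripsis as a *switch-density* criterion on a segmented,
discretized profile:

- `correct_log2()` removes whole-chromosome shifts by adding
  `log2(tumor_fraction / normal_fraction)` per chromosome;
- `discretize_states()` maps log2 ratios to integer states
  (`pmax(round(baseline * 2^log2), 0)`, baseline 2 for diploid);
- `count_switches()` finds, per chromosome, the maximal run of adjacent
  state changes that oscillates between exactly two states. A switch is
  a state change between adjacent segments inside such a run; the span
  is measured between breakpoint midpoints `(end_i + start_{i+1}) / 2`
  of the first and last switch, in Mb. Ties in switch count are broken
  toward the smaller span (the denser, more chromothripsis-like run).
- `call_chromothripsis()` calls a chromosome positive when the maximal
  run has **at least 6 switches** and a switch-per-Mb ratio **of at
  least 0.2** (both inclusive: a profile sitting exactly on the
  thresholds is positive). With fewer than 2 switches the ratio is
  defined as 0.

"Alternating" is deliberately strict — oscillation between exactly two
states — because monotone staircases (e.g. 1,2,3,4) are stepwise gains,
not shattering. The looser reading is available as
`policy = "any-change"`, which counts every adjacent state change; the
two policies agree on two-state profiles and are both tested against an
exhaustive window-enumeration oracle.

## ALT classification and telomere content

`classify_alt()` calls a sample ALT-positive from a C-circle assay when
the polymerase signal is at least **2×** the no-polymerase control *and*
at least **3×** the background, both inclusive; missing intensities give
`not_determined`, never an imputed call. The rule is scale-free (all
three intensities share arbitrary units), and the suite verifies
invariance under common rescaling. `ts_ratio()` computes telomere
content as `log2((tumor_T / tumor_S) / (control_T / control_S))`;
`alt_association()` relates ALT status to any binary feature by Fisher's
exact test, excluding `not_determined` samples and reporting how many
were excluded.

## Genotype classes, biallelic inactivation, WGD

`classify_cn()` maps allele-specific copy number (major, minor) to five
classes: `homozygous_deletion` (0,0); `normal_biallelic` (minor ≥ 1);
`LOH` (1,0); `CNN_LOH` (2,0); `higher_ploidy_LOH` (≥3,0).

`flag_biallelic()` combines these with per-gene lesions (SNV, indel,
fusion, microalteration, germline variant, deletion). A gene is
biallelically inactivated when it is homozygously deleted, or when the
minor allele is lost and the retained allele carries a damaging lesion,
or when both alleles of a biallelic gene are hit. For chrX genes in male
samples a single damaging hit suffices. Lesions with unknown allele
assignment in LOH genes are resolved *optimistically*: if the observed
VAF is congruent with the lesion sitting on the retained allele —
expected VAF `purity * mutated_copies / (purity * totalCN + 2 * (1 -
purity))`, tolerance 0.1 — or if no VAF/purity information is available,
the hit is counted. This matches how such calls are curated in practice
and errs toward sensitivity; the per-gene `evidence` string records the
reasoning.

`call_wgd()` flags whole-genome duplication when ploidy is **≥ 2.9** and
the length-weighted fraction of the genome with major copy number ≥ 2
exceeds 0.5. The 2.9 cutoff sits below the tetraploid ideal of 4 because
post-duplication losses erode ploidy, while clearly diploid genomes
(ploidy ≈ 2 plus focal gains) stay well under it. When the segments
cover less than half of an `assessable_size`, the call is `NA` rather
than a guess from unrepresentative regions.

## Variant filtering

`filter_snv()` applies seven rules in fixed order, reporting the full
set of failed rules per record rather than stopping at the first:
(1) ≥ 5 variant reads; (2) VAF ≥ 0.05 (inclusive); (3) single-strand
support in a sequencing error-profile context; (4) control coverage
≥ 10; (5) control variant fraction strictly below 1/30; (6) overlap with
low-mappability/blacklist regions; (7) simultaneous overlap with two or
more repeat classes. Records lacking control data get an `NA` verdict.
`filter_indel()` requires a `0/0` control genotype, passes `PASS` calls,
and discards `badReads`/`alleleBias`/`strandBias` calls only when VAF
< 0.10; unknown flags are retained with a warning so that new caller
versions degrade loudly, not silently.

## Synthetic cohorts

The `simulate_*` generators produce cohorts with the exact statistical
structure each stage assumes, plus ground-truth tables, so every
pipeline stage is testable end to end without patient data. They are
deterministic given `sim_config(seed = )`.

- `simulate_catalogs()`: counts drawn multinomially (fixed per-sample
  total) or as independent Poissons (totals vary, like real burdens)
  around `W %*% mix`.
- `random_signature_set()`: signature columns drawn from a symmetric
  Dirichlet with `alpha = 0.5`. This default is chosen on entropy
  grounds: Dirichlet(0.5) profiles average about 3.9 nats of entropy,
  the mid-range of real reference signatures (roughly 2–4.4 nats),
  whereas sharper settings (e.g. `alpha = 0.25`) are more peaked than
  nearly all real signatures.
- `simulate_profiles()`: positive chromosomes carry exactly 10
  alternating switches spanning 50 Mb (switch density exactly at the
  0.2/Mb threshold); negatives are flat or carry at most 5 sparse
  switches. The generator stresses the decision boundary on purpose.
- `simulate_telomere_tables()`: ALT prevalence defaults to 0.78, a
  typical high-ALT sarcoma cohort frequency; telomere-content ratios are
  drawn independently of ALT status, emulating the observed lack of
  correlation.
- `simulate_genotypes()`: covers all five genotype classes, plants
  lesions consistent with a known biallelic truth, and emits genome-wide
  segments at ploidy ≈ 4.15 (WGD) or ≈ 2.15 (diploid) across a
  `wgd_fraction` of samples (default 0.55).

What the generators do *not* emulate: mutation rate heterogeneity along
the genome, subclonal copy-number mixtures, purity-driven signal
attenuation in the C-circle assay, and sequencing artifacts beyond the
planted filter violations. Cohort sizes, mutation burdens, and the
default three-signature mixture are package choices sized for fast,
fully deterministic test suites, not estimates of any particular cohort.
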