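---
title: "Methods: gene-level cis-eQTL testing with permutation and contrastive FDR control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-level cis-eQTL testing with permutation and contrastive FDR control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisegene)
```

## The eGene identification problem

A cis-eGene is a gene whose expression level is associated with at least one
local genetic variant — by convention, a SNP within 1 Mb of the gene's
transcription start site (TSS). Given

* `Y`, the fully processed `n x p` individual-by-gene expression matrix,
* `S_j`, the `n x q_j` dosage matrix of local common SNPs for gene `j`, and
* `X`, the `n x K` matrix of known plus inferred covariates,

the working model for gene `j` is the linear model

    Y[, j] = b0 + S_j b1 + X~ b2 + e,

where `X~` is the true covariate matrix that `X` tries to capture and at most
a few entries of `b1` are nonzero. Gene `j` is an eGene exactly when `b1` has
at least one nonzero entry. The statistical difficulty is the two-layer
multiplicity: thousands of genes, each with up to tens of thousands of local
SNPs that are heavily linkage-disequilibrium (LD) correlated.

The established answer is a two-step framework: (1) a gene-level P value (or
score) that accounts for the within-gene SNP multiplicity; (2) an FDR
procedure across genes. The per-gene statistic throughout this package is the
maximum absolute **partial correlation** between expression and each cis SNP,
both residualized on `[1 | X]`. This statistic is in one-to-one monotone
correspondence with the minimum per-SNP linear-model P value
(`t = r sqrt(df) / sqrt(1 - r^2)`, `df = n - K - 2`), so "max |r|" and
"min p" are interchangeable; the package stores `|r|` and converts on demand
with `corr_to_pvalue()`. All correlations are computed as matrix
cross-products of unit-normalized residual columns, which is what makes the
permutation loops cheap: the total cost of either variant is `O(B p q̄ n)`
for `B` permutations and mean cis-SNP count `q̄`.

## The two testing variants

**Standard variant** (`run_standard()`): for each of `B` replicates
(default `B = 1000`; `B >= 100` recommended), the *raw* expression column is
permuted first and then residualized, and the max-|r| statistic is recomputed
against the fixed genotype residuals. This matches the direct permutation
scheme of classical permutation-based eGene callers. The gene-level P value
is the proportion `(1 + #{b : T_bg,b >= T_exp}) / (B + 1)`; q-values follow
Storey's procedure by default (see below) and genes with `q <= target_fdr`
are called eGenes.

**Clipper (contrastive) variant** (`run_clipper()`): expression is
residualized *once*, then the residuals are permuted. Per gene, the contrast
score `C_j = T_exp,j - mean_b T_bg,j,b` is computed; no P values are
involved. For `B = 1`, the experimental and background scores are
exchangeable under the null, so `C_j` is symmetric about zero for non-eGenes
and the FDR among `{C_j >= t}` can be estimated by the count ratio

    FDRhat(t) = (1 + #{j : C_j <= -t}) / max(1, #{j : C_j >= t}),

with the cutoff at the smallest observed `|C_j|` whose estimate is at or
below the target, ties discovered inclusively, and per-gene q-values defined
as the smallest estimated FDR over thresholds at or below the gene's own
contrast. The add-one numerator keeps the estimate strictly positive, and
its resolution is `1/#discoveries` — the variant therefore needs a
reasonable number of genes (hundreds) to operate, which is its intended
regime. It is recommended only for large sample sizes (`n > 450`), where a
single permutation suffices.

The permute/residualize *order* is a deliberate difference between the two
variants, implemented as genuinely separate code paths. One shared
permutation per replicate is applied to all genes; this preserves each
gene's marginal permutation null and enables the matrix-aggregated
implementation.

### Contrast aggregation for B > 1

With several background replicates the two natural aggregations behave very
differently, and we verified both before committing:

* `C_j = T_exp - max_b T_bg` makes the null contrast positive with
  probability only `1/(B+1)`; the count estimator then overestimates the FDR
  so badly that power collapses at the recommended `B` values. We rejected
  it.
* `C_j = T_exp - mean_b T_bg` — the "average of experimental minus average
  of background" contrast of the contrastive-FDR literature — keeps the
  contrast centered, but for `B >= 2` the experimental score and the
  background *mean* are no longer exchangeable, and the right skew of the
  max-correlation null makes the count estimator anti-conservative.

We therefore use mean aggregation with a dispatch on `B`: the count (BC)
estimator exactly as above for `B = 1`, and for `B >= 2` a Gaussian null fit
to the contrast scores (center from the median, spread from the 10th
percentile — both insensitive to right-tail signal), one-sided normal P
values, and Storey q-values. This mirrors the contrastive-FDR practice of
switching to a Gaussianized procedure when replicate numbers are unequal,
restores the robustness of results to the choice of `B`, and reduces to the
same rule at `B = 1`.

## FDR procedures

`storey_qvalue()` estimates the null proportion as
`pi0 = min(1, #{p > 0.5} / (0.5 m))` and returns monotone
`pi0 * m * p_(i) / i`; with `pi0 = 1` it reduces to Benjamini-Hochberg.
`bh_adjust()`/`by_adjust()` wrap `stats::p.adjust`. Storey at
`lambda = 0.5` is the default on gene-level P values, matching common eQTL
practice; BH and BY are selectable (`fdr_procedure`), which also covers the
Simes-based comparator in both its BY and Storey flavors.

## Comparator gene-level procedures

* **Beta approximation** (`beta_gene_pvalue()`, `run_comparator(method =
  "beta")`): fits `Beta(a, b)` by maximum likelihood (moment-matched start,
  Nelder-Mead on log-parameters) to the per-permutation *minimum* P values
  and evaluates its CDF at the observed minimum, interpolating a
  higher-resolution gene P value from moderate `B`. Non-convergence falls
  back to the proportions formula with a warning.
* **Effective-number-of-tests Bonferroni** (`eigenmt_gene_pvalue()`): SNPs
  are partitioned into consecutive windows of at most 200; per window the
  dosage correlation matrix is eigendecomposed and the smallest `k`
  explaining 99% of variance is the window's effective test count; the gene
  P value is `min(1, p_min * M_eff)`. Windows do not overlap (a documented
  divergence from tools that slide them); constant SNP columns are dropped.
* **Simes' rule** (`simes_gene_pvalue()`): `min_k m p_(k) / k`.
* **Naive all-pairs calling** (`naive_matrixeqtl_egenes()`): BH across all
  gene-SNP pairs, gene called if any pair is significant. This controls the
  *pair*-level FDR, not the gene-level one: true pairs concentrate in a few
  genes while false pairs spread across many, so its gene-level FDR is
  inflated. It is included as the miscalibrated baseline and our simulations
  reproduce the inflation.

## Choosing the number of expression PCs

`expression_pcs()` returns top PCs of the column-standardized expression
matrix (deterministic sign convention: the largest-magnitude loading of each
component is positive). Two selectors:

* **Parallel analysis / BE** (`choose_k_be()`): each gene column is permuted
  independently (20 permutations by default); the chosen `K` counts leading
  PCs whose observed variance explained exceeds the 95th percentile of the
  permuted variance explained at the same index, stopping at the first
  failure so the retained set is contiguous. Stop-at-first-failure avoids
  non-contiguous PC sets.
* **Elbow** (`choose_k_elbow()`): the scree index with maximum perpendicular
  distance from the chord joining the scree curve's endpoints; it is
  scale-invariant and returns 1 when fewer than 3 PCs exist. The chord
  construction is a convention — the literature cites "the elbow method"
  without a formula.

## The synthetic-data generator

`simulate_dataset()` emulates the benchmark design used throughout the
package's validation. Defaults: `n = 838` individuals, `p = 1000` genes,
`K = 20` standard-normal known covariates, 20% eGenes with one causal SNP
each, 500 cis SNPs per gene, MAFs uniform on (0.05, 0.5), target genotype
variance fraction `PVE_genotype = 0.02` in eGenes (cis effect only) and
covariate fraction `PVE_covariates = 0.5` in all genes.

Design notes:

* **Genotypes** are hard-call dosages obtained by thresholding latent AR(1)
  Gaussians at Hardy-Weinberg quantiles (a Gaussian copula). The AR
  parameter is `ld_rho = 0.9`, i.e. adjacent-SNP LD `r^2 ~ 0.75` at the
  ~10 kb SNP spacing the generator produces. This matters: common variants
  in real cis windows sit in strong LD blocks, which is precisely why the
  effective number of tests is far below the SNP count and why naive
  all-pairs calling loses gene-level calibration. With weak LD (e.g.
  `ld_rho = 0.5`, where adjacent-dosage correlation decays almost
  immediately at this spacing) each eGene contributes a single significant
  pair and the naive baseline becomes artificially well calibrated —
  the opposite of what real data show.
* **Effect scaling targets realized (in-sample) variance fractions**: the
  causal-genotype and covariate components are rescaled so their sample
  variances are exactly the configured fractions, so the PVE bookkeeping in
  `truth$realized_pve` is exact by construction up to cross-term noise.
  Monomorphic causal draws are resampled with a warning.
* **What it does not emulate**: population structure and relatedness,
  MAF-dependent LD, trans effects, non-Gaussian expression noise, and
  covariates correlated with genotype. Passing tests on these simulations
  therefore demonstrate calibration and ranking behavior under the model's
  assumptions, not robustness to those real-data complications.
* `evaluate_calls()` scores calls against truth as
  `FDP = false / max(1, discoveries)` and `power = true / #eGenes`.

## Numerical choices and degenerate inputs

* Residualization uses a QR-orthonormal basis of `[1 | X]`; rank deficiency
  is an error naming the collinear columns. `df = n - K - 2` is fixed in one
  place (`corr_to_pvalue()`).
* Residual SNP columns with zero norm (constant dosages, or dosages in the
  covariate span) are dropped per gene; a gene whose expression residual is
  degenerate is excluded with a warning and reported with `NA` results, and
  excluded from the multiple-testing denominator (as are genes with zero
  SNPs after filtering).
* MAF is folded (`min(m, 1-m)`, `m = mean(dosage)/2`); carrier counting for
  the minor-allele-samples filter counts dosage >= 0.5 *on the minor-allele
  scale*. Both SNP filters must pass (AND).
* The cis window is a closed interval `|pos - TSS| <= 1 Mb` on both sides;
  no strand adjustment beyond the TSS. Expression BED input takes
  `TSS = start + 1` (BED is 0-based half-open, with the TSS at the interval
  start).
* Permutations: one master seed generates the whole `n x B` permutation
  stream up front (`permutation_indices()`); results are bit-reproducible
  for a given seed. Exact results are *not* invariant to relabeling samples
  jointly in all inputs (the fixed stream composes differently with the
  relabeling) but are invariant in distribution; observed statistics are
  exactly invariant.
* Proportions P values carry the add-one rule, so exact zeros cannot occur
  and the beta fit (which needs minima strictly inside (0,1)) is safe.
* Clipper ties at the cutoff are all discovered; genes with nonpositive
  contrast get q = 1.

## Problem sizes used in validation

The packaged validation (test suite and `scripts/acceptance.R`) runs the
benchmark design at a reduced scale chosen to keep a full replication on one
CPU comfortable: 300 genes with 200 cis SNPs each at the full sample size
`n = 838`, 10 simulation replicates, `B = 200` for the standard variant and
`B = 1` for the Clipper variant. At this scale all P-value-based methods sit
near power 0.95–1.0 for the configured effect size, so *power differences*
between calibrated methods are at the resolution limit of the design
(roughly one gene, 1/60); the calibration contrasts (permutation methods vs
the naive all-pairs baseline) remain unambiguous.

## Known limitations

* The Clipper variant's count estimator needs enough candidate genes
  (its smallest attainable FDR is `1/#discoveries`); it is unsuitable for
  panels of a few dozen genes.
* Comparator implementations are deliberately reduced to their gene-level
  cores (Simes + across-gene FDR; windowed effective-test Bonferroni);
  hierarchical gene-to-SNP FDR control and adaptive permutation schemes are
  out of scope.
* Linear models only: related individuals (LMM territory) and count-level
  single-cell models (GLMMs) are not supported; single-cell data enter via
  pseudobulk aggregation (`pseudobulk()`), which normalizes each cell by
  `log(count / total * 1e4 + 1)` and averages per gene-individual in the
  de-logged space.
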