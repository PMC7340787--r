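---
title: "Methods: co-expression modules projected onto PPI networks"
author: "coexppi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules projected onto PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexppi)
```

## The problem and the model

Classical PPI module finders (clique percolation, MCODE-style density
search) carve a protein-interaction graph by topology alone. When the
question is *which targets of a drug matter for a particular disease*,
topology is not enough: the modules should reflect how genes co-behave in
the diseased tissue. `coexppi` therefore derives the partition from a
weighted gene co-expression network built on a tumor cohort and only then
projects it onto the PPI graph of candidate targets. Nodes that are both
(a) members of the module most associated with the clinical trait and
(b) connected in the target PPI network are the candidates, subsequently
filtered by differential expression and survival association.

The co-expression side follows the standard weighted-network recipe:

* **Soft adjacency.** `a_ij = |cor(x_i, x_j)|^β` (unsigned, default) or
  `((1+cor)/2)^β` (signed). β is an integer ≥ 1.
* **Scale-free criterion.** Connectivities `k_i = Σ_{j≠i} a_ij` are
  binned (10 equal-width bins), and log₁₀ frequency is regressed on
  log₁₀ mean connectivity; the fit index is signed, `−sign(slope)·r²`,
  so only *decreasing* degree distributions can satisfy the conventional
  `R² > 0.9` rule. The smallest candidate β that does so is chosen;
  otherwise the best-fitting β with a warning. On planted-factor
  synthetic data the degree distribution is not scale-free, so the
  warning path is the norm there — module recovery does not depend on it.
* **Topological overlap.** `ω_ij = (l_ij + a_ij) / (min(k_i,k_j) + 1 −
  a_ij)` with `l_ij = Σ_{u≠i,j} a_iu a_uj`; `1 − ω` is the clustering
  dissimilarity.

## Module detection: an adaptive cut validated by recovery

The reference "dynamic hybrid" branch cut is intricate; this package
implements a deliberate approximation and validates it by
planted-partition recovery (adjusted Rand index against known modules),
not by label-for-label agreement with any other implementation.

Average-linkage trees on `1 − TOM` are cut as follows: every candidate
cut height (midpoints between consecutive merge heights, subsampled to
150 when trees are large) is scored by

> Σ over branches with ≥ `min_module_size` leaves of
> `n_branch · (mean within-branch TOM − mean TOM)`,

and the best-scoring cut wins. The score is deliberately blind to branch
*count*: chance aggregates of background genes are no tighter than the
network at large and contribute ≈ 0, while a cut that fuses two real
modules (or lets background chain onto one) dilutes the within-branch
mean and loses to the cut that separates them. We moved to this criterion
after two simpler rules failed: maximizing the number of min-size
branches absorbs background genes at high cuts, and absolute-height
branch persistence collapses when a large β compresses the dendrogram
into a narrow height band near 1. `deep_split` (0–3) maps to a tolerance
(0/2/5/10% of the best score) within which the *finest* cut is preferred.
Two repair stages follow when the expression matrix is available:
unassigned genes join the module whose eigengene they correlate with at
module membership > 0.3 (background genes at realistic sample sizes sit
4σ+ below that bar), and modules whose eigengenes correlate above
`1 − merge_height` (default cor > 0.75) are merged, which also undoes
over-splitting. Modules are named by size-ordered colors ("turquoise"
largest); `grey` is reserved for unassigned genes. Labels are cosmetic —
tests compare partitions.

Module eigengenes are first-principal-component sample scores of the
standardized module submatrix, scaled to unit sample variance and
sign-oriented to correlate positively with the module's mean expression
(PCA sign is otherwise arbitrary). Module–trait association uses Pearson
r with the two-sided Student p on n − 2 df; gene significance (GS) is the
gene–trait correlation (signed; rank by |GS|), module membership (MM) the
gene–eigengene correlation. The critical module is the largest-|r|
module with p < α for the chosen trait; ties break by smaller p, then
larger module.

## PPI projection

PPI edges are kept at `combined_score ≥ 0.4` ("medium confidence",
inclusive; the 0–999 STRING dialect is divided by 1000). The projected
network keeps edges whose *both* endpoints carry a non-grey module label;
its node set is edge-defined (isolated labeled genes drop out — a flag
keeps them for sensitivity analysis), nodes carry module labels and
degrees, and critical-module nodes ordered by degree are the candidate
targets. Only shared module membership is required of an edge; a
TOM-weight floor on edges was considered and rejected as an extra
parameter the projection does not need — the co-expression evidence
already acted through the partition.

## Validation statistics

* **Differential expression**: two-sided Wilcoxon rank-sum, tumor vs
  normal; exact enumeration when the pooled sample is ≤ 12 and tie-free,
  otherwise normal approximation with tie and continuity corrections. At
  12 + 12 samples the approximation is within 0.007 of the exact p over
  the whole null distribution; at 6 + 6 it can deviate by 0.016, which is
  why the exact path exists.
* **Survival**: samples split at the median expression of the candidate
  (ties at the median go "low" — deterministic, unbiased; "best cutoff"
  scanning was rejected as a multiple-testing hazard). Kaplan–Meier
  product-limit curves and the standard two-group log-rank χ² on 1 df.
  A candidate passes at Wilcoxon p < 0.05 *and* tumor median higher,
  plus log-rank p < 0.1 *and* worse survival in the high group. The
  lenient 0.1 survival threshold is retained deliberately as the
  convention of the workflow this package operationalizes.
* **ORA**: plain upper-tail hypergeometric p with BH adjustment — *not*
  the EASE-modified (k − 1) score some web services report; results
  differ slightly from those by construction.
* **GSEA**: signal-to-noise ranking `(μ₁−μ₀)/(σ₁+σ₀)` with each σ
  floored at `max(0.2·|μ|, 0.2)` (the desktop convention), weighted
  running sum (hit weight `|score|^p`, p = 1; misses `−1/(N−N_hits)`),
  ES = signed maximum deviation. Phenotype labels are permuted (the
  default appropriate for ≥ 7 samples per group; gene-set permutation is
  available by flag), with exact enumeration when fewer distinct label
  assignments exist than requested permutations. Nominal p uses the
  add-one rule over same-sign permutation scores (never 0, minimum
  `1/(n_perm+1)`); NES divides ES by the mean same-sign |ES|; FDR follows
  the pooled same-sign NES rule.

## The synthetic world

The generator states one cohort and is not re-tuned per test:

| parameter | default | meaning |
|---|---|---|
| n_genes × n_samples | 500 × 200 | desk-scale tumor cohort |
| module_sizes | 60, 50, 40 | planted modules; 350 background genes |
| factor loadings | U(0.6, 0.9) | `x = λf + √(1−λ²)ε`, unit variance rows |
| trait point-biserial | 0.32 | module-1 factor vs binary recurrence |
| targets | first 3 genes of module 1 | survival-driving genes |
| log hazard ratio | 1 per SD | exponential hazard on mean target expression |
| baseline hazard | 0.05 / month | median survival ≈ 14 months at z̄ = 0 |
| censoring | 30% | independent exponential, rate solved to match |
| PPI | 0.9 within / 0.02 between | Bernoulli edges, scores U(0.4, 1) |
| PPI coverage | 0.02 (+ targets) | drug-target universe, see below |
| normal cohort | 50 samples, targets −1.5 SD | tumor-vs-normal ground truth |

Noise scale for the binary trait is calibrated by grid search so the
realized point-biserial correlation with the factor hits the target; the
censoring rate is matched by solving `mean(r_c/(r_c+h_i)) = rate` for the
censoring hazard. Age and grade are uninformative nuisance columns.

Two defaults deserve justification. *PPI coverage*: a drug-target PPI
network covers a small slice of the expressed genome (in the motivating
study, 471 PPI nodes against 13,512 expressed genes, ≈ 3.5%). The
synthetic universe therefore samples 2% of genes plus the targets. This
is not cosmetic: with a PPI spanning all genes the mapped critical module
would carry ~60+ candidates, and the Wilcoxon filter's type-I error alone
(α·½ per null candidate) would make "final targets = exactly the planted
three" statistically unreachable — no method could pass, because the
world, not the method, would be wrong. *Normal-cohort shift* (1.5 SD,
50 samples) gives the planted targets essentially full Wilcoxon power at
α = 0.05 while leaving every other gene exactly null.

What a green test does *not* establish: the generator draws factors and
noise i.i.d. Gaussian with unit-variance genes, so it does not emulate
microarray probe artifacts, normalization residue, correlated noise,
batch structure, heavy tails, or hub-like scale-free PPI topology.
Recovery results here bound what the pipeline can do under its own
assumptions, not on arbitrary real data.

## Numerical choices and degenerate inputs

* All randomness flows from one integer seed through named substreams;
  the caller's RNG state is restored afterwards. Same seed ⇒ byte-equal
  outputs.
* Correlation of a constant gene is an error naming the gene (adjacency),
  or drops the gene with a warning (eigengene PCA). Zero-variance traits
  are flagged and reported as r = 0, p = 1.
* TOM denominators are guarded (`ω = 0` when ≤ 0, diagonal 1, symmetry
  enforced against floating-point drift); equal-connectivity networks are
  flagged with fit index 0 rather than fitted.
* Variance-filter ties break lexicographically by gene id; degree ties in
  node ranking likewise. Sample-outlier flagging uses leave-one-out
  moments of the leaf merge heights (a pooled mean + k·sd rule lets a
  single extreme sample mask itself by inflating the sd) and refuses to
  flag more than 20% of samples.
* Imputation is by gene median — robust, deterministic, and the matrix
  is assumed already normalized (probe-level processing is out of scope;
  a maximal-variance probe collapser is provided for platform matrices).
* The pipeline persists every stage output as TSV, checksums it, and
  re-verifies the checksums at the end of the run; reports are
  reproducible byte-for-byte under a fixed config and seed.

## Known limitations

* Desk scale: dense gene × gene matrices, no blockwise decomposition —
  intended for ≤ ~5,000 genes after variance filtering.
* The adaptive cut is a validated approximation, not a reimplementation,
  of the reference dynamic hybrid algorithm; exact module counts on any
  specific real dataset depend on unstated sub-parameters there
  (signedness, deep split, merge height) and are treated as soft targets.
* No Cox regression or hazard-ratio confidence intervals; the survival
  screen is the two-group log-rank only.
* Identifier harmonization between expression and PPI spaces is the
  caller's responsibility (an id-mapping file contract replaces live
  lookup services); no web services are contacted anywhere.
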