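---
title: "Methods: the candidate-gene cascade and cell-shape morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the candidate-gene cascade and cell-shape morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterophylly)
```

## The problem

Heterophylly — one genotype, two leaf forms depending on whether the
shoot develops in air or under water — poses a gene-discovery problem
with an unusual shape. The treatments that block submerged-leaf
formation (AgNO₃ for ethylene signaling, uniconazole P for gibberellin
synthesis, ABA) each perturb thousands of genes, far more than can
plausibly drive the leaf switch. The analysis implemented here narrows
the field by intersecting *direction-consistent* differential calls
across conditions and then subtracting everything that a
nonheterophyllous sister species does identically. The cellular
phenotype that the candidates must explain — jigsaw-lobed versus
elongated cells — is quantified by polygon morphometrics.

## The differential-expression model

Counts for gene $g$ in sample $j$ are modeled as negative binomial with
mean $\mu_{gj}$ and dispersion $\phi$, $\mathrm{Var} = \mu + \phi\mu^2$;
$\phi = 0$ is the Poisson limit. The pipeline is a single, desk-scale
equivalent of the usual TMM + exact-test stack, implemented rather than
called so that every step is observable and testable:

* **Filtering.** TPM is computed per sample
  ($10^6 (y/\ell) / \sum_g y/\ell$, with $\ell$ the effective length);
  a gene is kept if its TPM reaches 1 in at least one sample. The filter
  is applied across *all* samples of a species, so every comparison of
  that species shares one gene universe — this is what lets the cascade
  intersect DEG tables without reconciliation.
* **Normalization.** TMM factors with the conventional trims (30%
  two-sided on the log-ratio M, 5% on the abundance A), inverse-variance
  weights from the delta method, reference sample chosen as the one whose
  upper-quartile expression is closest to the mean upper quartile, and a
  final rescaling to geometric mean 1. The test suite cross-checks the
  factors against an independent implementation; tiny discrepancies
  (≈10⁻⁴, boundary ties at the trim quantiles between rank-based and
  quantile-based trimming) are tolerated.
* **Dispersion.** A common $\phi$ by method of moments: per-gene pooled
  within-group residuals on normalized counts give
  $\hat\phi_g = (s^2 - \bar y)/\bar y^2$, aggregated by the median over
  genes with normalized mean ≥ 1 and floored at zero. This
  deliberately simple estimator stands in for heavier likelihood
  machinery; simulations at known $\phi$ bound its error well inside
  what the decision rule tolerates.
* **Testing.** The conditional exact NB test: with $n_A$ and $n_B$
  samples per group at common mean, group sums are NB, and the group-A
  sum conditioned on the grand total $t$ has a ratio law that we
  enumerate over $s = 0..t$. The two-sided p-value sums the
  probabilities of all outcomes no more likely than the observed one
  (with a $1 + 10^{-8}$ relative guard against ties lost to floating
  point). Counts are first rescaled to a common effective library size
  and rounded. For $t$ above an enumeration cap (default 5000, the
  `enum_cap` configuration) a normal approximation to the conditional
  law with continuity correction takes over; at that depth the discrete
  law is indistinguishable from its Gaussian limit at the tolerances of
  the decision rule. A grand total of zero carries no information and
  returns p = 1 with a warning.
* **Decision rule.** BH-adjusted q strictly below 0.05 *and* |log₂
  fold-change| strictly above 1, signed by the fold-change. Fold-changes
  are ratios of normalized group means with a 0.5 pseudo-count added to
  each mean so zero groups stay finite.

## The cascade and its conventions

The submerged control is the denominator of every fold-change, so "up"
always means higher under the treatment (aerial-like) condition.
"Consistent change" is interpreted as equal log₂ fold-change sign across
comparisons — the natural reading of DEG sets split into up- and
down-regulated panels.

The cross-species exclusion applies two rules in a fixed order of
precedence: (1) a candidate with a comparable ortholog (one-to-one or
one-to-two between the diploid and the tetraploid) that is a DEG in the
diploid with the *same direction* is excluded — shared behavior implies
no role in the divergent phenotype; (2) a candidate that is
*downregulated in submerged* primordia whose ortholog is not expressed
(TPM below the floor in every diploid sample) is excluded — losing the
expression of a gene the relative never expresses cannot explain the
leaf switch. Candidates without a comparable ortholog are always
retained. Three conventions are worth stating because the source
analysis leaves them open:

* **One-to-many propagation.** A diploid DEG excludes *all* of its
  tetraploid co-orthologs: the test is per link. The conservative
  alternative (exclude only if all co-orthologs agree) would retain
  genes whose duplicate copies diverged; we prefer the stricter rule
  because the exclusion logic treats the diploid gene, not the copy, as
  the unit of evidence.
* **"Not expressed."** Operationalized as TPM < 1 in all diploid
  samples, reusing the analysis' own expression floor rather than
  inventing a second threshold; configurable via `tpm_threshold`.
* **Orthologs missing from the diploid DEG table** are treated as
  non-DEGs rather than as errors: the low-expression filter removes them
  legitimately (indeed the unexpressed-ortholog rule is *about* such
  genes). Absence from the TPM table, by contrast, is a hard error.

Stage specificity is a simple partition: a candidate that is a DEG
(either sign) in the mature aerial-vs-submerged comparison is
`dev_and_mature`, otherwise `dev_specific`. The same FDR/fold-change
rule governs all comparisons.

## Enrichment

One-sided hypergeometric over-representation only; the analysis reports
enrichment, not depletion. Rare terms (population count below 5) are
removed *before* testing: the omission is part of the analysis design,
and testing fewer hypotheses is the coherent reading — the suite
demonstrates on a constructed case that filtering after BH gives
different q-values. Namespaces can be tested separately via the
`namespace` argument. One subtlety the tests encode: removing a study
gene *annotated to a term* never strengthens that term (its p never
decreases), but removing an unannotated gene shrinks the draw and can
make every other term's p smaller — the monotonicity property only holds
per annotated term.

## Morphometrics

All descriptors are computed on the polygon, not on pixel masks:

* area and perimeter by the shoelace formula (orientation invariant);
* circularity $4\pi A / P^2$, clipped at 1 because discrete polygons can
  exceed it numerically (the convention of the imaging software the
  measurements emulate);
* solidity as area over convex-hull area;
* the best-fit-ellipse aspect ratio from *exact interior* second-order
  central moments (Green's theorem over the boundary), not vertex point
  moments — vertex density then cannot bias the estimate;
* the minimum bounding rectangle as the minimum-**area** rotated
  rectangle via rotating calipers over the hull (the optimum has a side
  collinear with a hull edge). This is the rotation-free cell
  length/width, not the axis-aligned box.

Degenerate inputs (fewer than three vertices, zero area, self-
intersection when checking is enabled) raise errors rather than NaNs.
The statistical layer adds Welch's t (p = 1 by convention when both
groups are constant and equal), Hedges' g with the small-sample
correction $J = 1 - 3/(4(n_a+n_b-2)-1)$, Tukey–Kramer HSD with an
insert-and-absorb compact letter display, and PCA on descriptors
standardized to unit variance — the descriptors carry different units,
so correlation-matrix PCA is the defensible default even though the
source analysis does not state its scaling.

## What the generator emulates — and what it does not

`simulate_experiment()` produces the full two-species bundle under the
study's design: five primordium conditions plus two mature-leaf
conditions for the tetraploid (three replicates each, the study's
sibling-plant design), aerial/submerged primordia for the diploid, an
orthology map whose one-to-two fraction mirrors the roughly half of
diploid genes with duplicated tetraploid co-orthologs, and planted
categories at the emulated study's category sizes (200 + 87 shared candidates,
22 + 15 exclusions, 145 retained genes without orthologs, 208 ORFs, 19
TFs of which 5 submerged-upregulated, 134 mature-shared). Planted
effects are |log₂FC| = 2 at baseline mean 100 and $\phi = 0.05$;
library depth is a 5×10⁶-count-equivalent total with log-normal
per-sample factors (CV 0.1). Depth and dispersion are configuration, not
claims — no reference values exist for them — and the effect size
is chosen so that planted genes sit comfortably past the fold-change
threshold at three replicates, which is what "planted ground truth"
requires of a recovery test.

The generator deliberately does not emulate: read-level artifacts
(mapping bias, multi-mapping between duplicated copies — precisely the
hard part of tetraploid quantification), correlated genes or modules,
gene-specific dispersion trends, outlier samples, or composition bias
beyond what the planted asymmetric signatures induce. Passing the
recovery tests therefore shows the *logic* of the pipeline is correct
under its stated model, not that the model captures every pathology of
real sequencing data.

Cell contours come in four parametric classes; the lobed class uses
$r(\theta) = R(1 + a\sin k\theta)$ (amplitude $a \in [0, 0.5)$ keeps the
polygon simple and star-shaped), with defaults $a = 0.3$, $k = 8$ for
jigsaw pavement cells, a circle for round palisade cells, and a 5:1
ellipse for submerged elongated cells — separations chosen to give
effect sizes |g| > 1, the qualitative contrast the real measurements
show. Radial jitter (3%) is resampled until the polygon stays simple.
Noiseless analytic descriptors ride along as oracle values.

## Problem sizes and numerical tolerances used by the suite

The tests run the DE stage at 2000 genes and 3 vs 3 replicates (type-I
error within [0.03, 0.07] at known $\phi$; ≥ 90% sensitivity and ≤ 10%
empirical FDR at planted |log₂FC| = 2), exact-test equality against
brute-force conditional enumeration at grand totals ≤ 200 (10⁻¹⁰),
hypergeometric equality against exhaustive enumeration at N ≤ 30
(10⁻¹²), shape-descriptor analytics under arbitrary rotation (10⁻⁹;
bounding rectangles against a 3600-angle brute-force sweep at 10⁻⁶),
and the full pipeline end to end at 10⁴ genes across five seeds
(≥ 95% agreement with the planted truth). These sizes are the package's
own choices: large enough that the binomial/large-number bounds in the
assertions are meaningful, small enough that the whole suite runs in
about two minutes.

## Known limitations

* The common-dispersion estimator ignores mean-dispersion trends; with
  strong trends the exact test is conservative for high-count genes and
  liberal for low-count ones.
* TCC-style iterative DEG-elimination normalization is intentionally not
  implemented; with the planted asymmetric signatures TMM's trimming
  absorbs the composition bias, but data where >30% of genes move in one
  direction would defeat the trim.
* The orthology map is consumed as input truth; mis-assigned orthologs
  propagate directly into wrong exclusions, and nothing in the cascade
  can detect them.
* The letter display is the greedy insert-and-absorb algorithm; it is
  correct (groups share a letter iff not significantly different) but
  not guaranteed minimal in letter count.
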