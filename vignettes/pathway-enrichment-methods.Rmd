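---
title: "Methods: gene-based pathway enrichment for stratified case/control GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-based pathway enrichment for stratified case/control GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`pathperm` asks a pathway-level question of case/control genotype data: are
the genes of a candidate pathway (the motivating application is the
nuclear-encoded oxidative-phosphorylation machinery in lacunar stroke)
over-represented among the most disease-associated genes, and is that
enrichment specific to a radiologically defined case stratum? The pipeline
has four statistical stages, each behind its own function, orchestrated by
`run_study()`:

1. **Quality control** — per-variant and per-sample filters plus iterative
   principal-component (PC) ancestry-outlier removal.
2. **Per-SNP association** — a logistic score test of additive dosage with
   the first two PCs as covariates, run per phenotype contrast (all cases,
   MLI/LA-like cases, ILI-like cases; controls shared).
3. **Gene-level statistics** — the sum of per-SNP 1-df chi-squared statistics
   in a gene +/- 50 kb window, with an empirical p-value from a
   multivariate-normal null that respects the gene's LD structure.
4. **Enrichment** — permutation tests counting pathway genes in the top
   1/5/10% of the gene ranking, plus a GSEA-style weighted running sum, with
   a Bonferroni threshold of 0.05/12 = 0.0042 across the 3 x 4 grid of
   contrasts and tests.

# Models and statistics

## Score test

For dosage $g_i \in \{0,1,2\}$ and status $y_i$, the null logistic model
$\operatorname{logit} P(y=1) = \beta_0 + \gamma^\top z_i$ (covariates $z$,
no genotype term) is fitted by Newton-Raphson; the score statistic for the
dosage term is

$$ T = \frac{U^2}{V}, \quad U = \sum_i g_i (y_i - \hat\mu_i), \quad
   V = g^\top W g - g^\top W Z (Z^\top W Z)^{-1} Z^\top W g $$

with $W = \operatorname{diag}(\hat\mu_i(1-\hat\mu_i))$. $T$ is compared to
$\chi^2_1$. With an intercept-only null this is exactly the Cochran-Armitage
trend test, which the test suite checks to $10^{-8}$. Samples with a missing
dosage are dropped per SNP and the null model is refitted on the retained
subset (warm-started from the full-sample fit), so a SNP's statistic depends
only on samples with observed genotype. SNPs that are monomorphic in the
analysis subset, or retain fewer than two cases or two controls, are flagged
untestable and excluded from gene sums rather than contributing a zero: a
zero would deflate gene statistics non-informatively.

## Gene-level empirical p

A gene's observed statistic is $S = \sum_{j \in \text{gene}} T_j$ over the
SNPs in its window. Under the null and local LD, the vector of per-SNP
$Z$-scores is approximately multivariate normal with covariance equal to the
dosage correlation matrix $R$, so the null of $S$ is the distribution of
$\sum_j X_j^2$, $X \sim \mathcal N(0, R)$. We draw from this distribution
(Cholesky factor of $R$; eigendecomposition fallback for repaired matrices)
and report $\hat p = \#\{S^{sim} \ge S\}/n_{sim}$ — a plain proportion, ties
counted as exceedance, so $\hat p$ can be exactly 0 or 1. A
$(r+1)/(n+1)$-style estimator is available behind the `plus_one` flag.

Two closed-form limits anchor the implementation and the tests: identity
correlation gives $S \sim \chi^2_k$, and an all-ones correlation collapses
the gene to a single variable with $S/k \sim \chi^2_1$.

$R$ is estimated from the full post-QC study genotypes (no external LD
reference is used; the estimate is shared across contrasts and cached). It
is repaired to positive semi-definiteness by flooring eigenvalues at
$10^{-8}$ and rescaling to unit diagonal; this is required whenever a window
contains duplicated or near-duplicated SNPs, or when pairwise-complete
estimation under missingness produces a slightly indefinite matrix.

Simulation counts escalate through a schedule (default $10^3 \to 10^4 \to
10^5$) until at least 10 exceedances are observed, so small p-values retain
bounded relative error without paying the maximal cost for every gene.

## Window mapping

A gene's window is its annotated body extended by 50 kb on each side,
boundaries inclusive, measured on the gene bounds given in the BED input
(transcript-level bounds are not modelled). A SNP may belong to several
windows; genes with no post-QC SNP are dropped from the gene universe and
therefore from enrichment denominators.

## Percentile permutation test

With a universe of $N$ genes ranked by ascending gene p (ties broken by
larger observed sum, then gene id), the top-$q\%$ cut contains
$m = \operatorname{round}(qN/100)$ genes (half-up, minimum 1). For a pathway
with $k$ genes in the universe and $X$ of them in the cut, significance is
assessed against random draws of $k$ genes from the universe: 1,000 draws
initially, escalated to 10,000 with a fresh derived seed when the initial
p-value is below 0.05. Because the draws are uniform without replacement,
the permutation null is exactly hypergeometric — the suite verifies the
permutation p against $P(\mathrm{Hyper}(N, m, k) \ge X)$ at 3 Monte-Carlo
standard errors. Random sets are matched on gene count only; matching on
SNP count or gene length is deliberately not attempted, so the known
size-confounding of count-matched null sets is inherited rather than
corrected.

## GSEA running sum

Genes are ranked as above and scored $s = -\log_{10} \hat p$ (zero empirical
p-values are floored at $0.5/n_{sim}$, the half-quantum of the simulation).
Walking down the ranking, the running sum gains
$|s|^w / \sum_{\text{set}} |s|^w$ at pathway genes (weight $w = 1$) and
loses $1/(N-k)$ elsewhere; the enrichment score is the running-sum value at
its maximum deviation from zero. The null uses the same random-set draws as
the percentile test (gene-score permutation, not phenotype permutation), and
the same escalation rule.

## Multiplicity and follow-up

The report has exactly 12 primary cells: 3 phenotype contrasts x
{top-1%, top-5%, top-10%, GSEA}. Each cell is called significant below
$\alpha^* = 0.05/12 = 0.0042$ (reported at 4 decimals alongside full
precision). Subcomplex scans (the five OXPHOS-like complexes in the
synthetic sets) run as follow-up only in strata whose top-1% test is
significant — they are reported raw and never enter the 12-cell family. A
`force_subcomplex` setting overrides the gating.

# The synthetic cohort generator

`simulate_study()` emulates the data the pipeline consumes, not human
genetics in general:

* **Genotypes.** Each gene is an LD block: two latent haplotype vectors per
  individual follow a stationary AR(1) Gaussian process (default adjacent
  correlation 0.8) thresholded at the allele-frequency quantile; dosage is
  their sum. Sites are therefore in Hardy-Weinberg equilibrium by
  construction and LD decays geometrically within blocks and vanishes
  between genes. MAFs are uniform on [0.05, 0.5] by default.
* **Genome layout.** Genes are tiled 1,000 per synthetic chromosome with
  20 kb bodies and 100 kb gaps, so +/- 50 kb windows of neighbouring genes
  are disjoint — as is typical for human pathway genes, which are rarely
  within 50 kb of one another. Multi-gene SNP sharing is exercised by tests
  with denser tilings; with dense tiling, neighbours of a causal gene
  hitchhike on its SNPs, which is faithful to the method but unrepresentative
  of a dispersed pathway.
* **Phenotypes.** ILI-like cases, unclassified cases and controls are
  population draws. MLI/LA-like cases are rejection-sampled from a logistic
  liability whose intercept solves the baseline prevalence (default 0.1) and
  whose per-allele log-odds is $\log(\text{OR})$ at each causal SNP — so any
  planted pathway effect exists only in the MLI/LA-like stratum, mirroring
  the stratum-specific hypothesis the pipeline is designed to probe.
* **Nuisance structure.** Optional two-subpopulation Balding-Nichols
  frequency divergence, completely-at-random missingness (default 1%), a
  configurable strand-ambiguous allele fraction (default 5%), and an
  injection helper for case-only missingness to exercise the differential
  missingness filter.

What the generator does **not** emulate: coalescent genealogies and
realistic long-range LD, allele-frequency spectra, imputation dosage
uncertainty, genotyping batch effects, related individuals (beyond
duplicated-sample constructions in tests), sex chromosomes, and
non-additive effects. Passing recovery tests on these cohorts therefore
demonstrates the statistical machinery, not robustness to every artefact of
real array data.

# Quality-control details

Defaults follow common exome-array GWAS practice: exclude variants with
MAF < 0.01, missingness > 3%, exact Hardy-Weinberg p < 1e-6 in controls
(Levene-Haldane test, mid-outwards recurrence), strand-ambiguous A/T-C/G
pairs, or case/control differential missingness at p < 0.05 (two-sided exact
2x2 test — per-SNP missing counts are routinely tiny, so an asymptotic
chi-squared would be unreliable). Samples are excluded for missingness > 3%,
heterozygosity |z| > 3 SD (no standard cutoff exists; 3 SD is the common
choice and is configurable), or relatedness: for each pair with
method-of-moments pi-hat > 0.1875 (worst pair first) the higher-missingness
member is dropped, ties by removing the lexicographically later id.

Pi-hat deserves a caveat at desk scale: with only a few thousand LD-blocked
SNPs the estimator's sampling noise is of order 0.03-0.07, and its right
tail occasionally crosses 0.1875 for truly unrelated pairs, removing a
small random subset of samples (a fraction of a percent to a few percent of
a clean cohort, shrinking as variant count grows). Real arrays with 10^5
pruned markers do not have this problem. The removals are status-independent
and so cost a little power but no validity.

PCA uses EIGENSTRAT standardization — centre by $2\hat p$, scale by
$\sqrt{2\hat p(1-\hat p)}$, missing entries at the column mean — on an
LD-pruned variant set (greedy sliding window on $r^2 > 0.2$; the pipeline
default window of 32 SNPs stepping 16 comfortably covers the generator's
4-SNP blocks). Up to 8 iterations remove samples more than 6 SD from the
mean on either of the first two components, stopping early when an
iteration removes nobody; the components returned are recomputed on the
final retained set and feed the association model. Component signs are
fixed by making each component's largest-magnitude loading positive;
results are invariant to sign flips regardless. A sex check is documented
as out of scope: the synthetic genomes are autosome-only.

# Numerical and reproducibility choices

* Every stochastic stage derives its own seed from the master seed and a
  stage label (`derive_seed()`), so per-gene simulation streams are
  independent of execution order, and re-running any stage in isolation
  reproduces its pipeline result. Gene members are put in canonical
  position order before simulation, making results invariant to input
  ordering.
* Per-SNP null refits under missingness use Newton iterations warm-started
  at the full-sample coefficients (convergence tolerance $10^{-10}$);
  the complete-dosage majority of SNPs shares a single null fit and is
  scored by matrix operations.
* The differential-missingness and HWE exact tests use a `(1 + 1e-10)`
  relative tolerance when comparing point probabilities, the standard guard
  against ties lost to floating-point rounding.
* Degenerate inputs are rejected with named errors: empty strata, missing
  controls while control-conditional filters are enabled, zero-variance LD
  members, sets empty after universe intersection, sets covering the whole
  universe (GSEA's miss decrement is undefined there).

# Calibration experiment design

The acceptance suite runs two simulation studies whose sizes were set by
design, before any results were inspected, and are part of the package's
documented conditions:

* **Null calibration** (200 replicate cohorts; 150 controls, 75 + 75 cases,
  800 genes x 4 SNPs, pathway of 80, no missingness for speed). The top-1%
  test's null is hypergeometric and therefore discrete: with $N = 800$,
  $m = 8$, $k = 80$ the attainable rejection rate at nominal 0.05 is
  $P(X \ge 3) = 0.037$, the closest achievable to 0.05 among desk-scale
  layouts (smaller universes can only reject at 0.015 or below). The
  observed rate is required to fall in the 99% binomial band around 0.05,
  which the discrete target satisfies with margin.
* **Dissociation recovery** (50 replicate cohorts; 200 controls,
  100 + 100 cases, 8 causal genes of the 80-gene pathway, 3 causal SNPs per
  gene at OR 2.0). A per-allele OR of 2 at common variants is deliberately
  strong — these cohorts are an order of magnitude smaller than a real
  GWAS, and the experiment tests recovery of a planted qualitative pattern
  (MLI/LA-like stratum significant at 0.0042, ILI-like stratum above 0.05),
  not effect-size realism. With $N = 800$, significance at 0.0042 requires
  at least 5 of the 8 top-percentile slots to be pathway genes.

The same arithmetic explains why enrichment p-values from small universes
live on a coarse grid: reports should be read with the attainable support in
mind.

# Known limitations

* The MVN gene null assumes the score statistics are jointly normal with
  covariance equal to dosage correlation; rare variants and small strata
  weaken this, as for any VEGAS-style method.
* Random null sets are count-matched only (see above).
* The LD reference is the study itself; no external panel mode exists.
* Summary-statistic-only input (no genotypes) is unsupported, since the LD
  matrix is estimated from the data.
* The generator's effect sizes are free parameters: nothing calibrates them
  to a published effect scale, and absolute power numbers from the
  synthetic studies do not transfer to real cohorts.
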