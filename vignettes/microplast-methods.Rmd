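---
title: "Quantifying microenvironmental plasticity in individual-level RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microenvironmental plasticity in individual-level RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microplast)
```

## The problem

Individuals of an identical, inbred genotype reared in a nominally common
environment still differ in gene expression. When each individual is
sequenced separately — rather than pooled — those differences become
measurable, and two questions follow. First, which genes differ in *mean*
expression among genotypes, sexes, replicate environments, and their
interactions? Second, which genes differ in *variability* among genetically
identical individuals within a cell of the design — the microenvironmental
plasticity of expression — and is that variability itself under genetic
control?

`microplast` implements the full analysis for a balanced factorial of
`G` genotypes x `S = 2` sexes x `R` replicate environments with `n`
individually sequenced flies per cell (defaults 16 x 2 x 3 x 8 = 768
individuals), together with a negative-binomial simulator that generates
matched synthetic data, so every stage of the pipeline is testable without
any external dataset.

## The count model and the testing ladder

Read counts for gene *i* in sample *k* are modeled as negative binomial
with mean `mu_ik` and variance

    sigma2_ik = mu_ik + phi_i * mu_ik^2,

`phi_i >= 0` the gene's dispersion (`phi = 0` recovers the Poisson). Means
follow a log-linear model with log size-factor offsets:

    log(mu_ik) = b0 + S + G + R + G:R + G:S + R:S + G:R:S.

Each term is tested by the difference in deviance between a full and a
reduced fit of a nested ladder:

| term tested | full model | reduced model |
|---|---|---|
| S, G, R | `S + G + R` | same, with the tested term deleted |
| G:R | `S + G + R + G:R` | `S + G + R` |
| G:S | `... + G:S` | `... + G:R` |
| R:S | `... + R:S` | `... + G:S` |
| G:R:S | full three-way | all two-way |

Both fits share one per-gene dispersion, estimated once under the full
three-way model, which is what makes the deviance difference a valid
likelihood-ratio statistic; p-values come from the chi-square upper tail at
the rank difference, and FDR is controlled per term across genes
(Benjamini–Hochberg), mirroring how term-wise significant-gene counts are
conventionally reported for this design.

### Dispersion estimation

`estimate_dispersion()` maximizes the *Cox–Reid adjusted* profile
likelihood in `log(phi)` (golden-section search on `[1e-6, 25]`, inner IRLS
warm-started across evaluations), with the pooled within-cell
method-of-moments estimate `max(0, (s^2 - m)/m^2)` as a fallback when the
likelihood fit fails, and a hard return of 0 for under-dispersed genes. The
adjustment term `-0.5 * logdet(X'WX)` matters here: the fullest model has
96 mean parameters for 768 observations, and the unadjusted profile MLE is
biased low by roughly the factor `(n - p)/n`, which would inflate every
LRT. With the adjustment, the median of `phi_hat/phi` in our recovery
simulations is within 1% of 1. No shrinkage across genes is applied: each
gene's dispersion is its own, which keeps the estimator transparent and
exactly testable (tools that model a mean–dispersion trend will differ,
usually by being less variable and slightly biased for atypical genes).

### Calibration at the study's cell size

A finite-sample caveat that users of deviance LRTs should know: with only 8
observations per design cell, the three-way interaction statistic (the
near-saturated comparison) is intrinsically inflated. In our null
simulations at the default design, plugging in the *true* dispersion gives
a mean statistic of about 34.6 against 30 degrees of freedom (rejection
0.145 at alpha = 0.05) — a Bartlett-type excess. Estimating the dispersion
per gene with the Cox–Reid adjustment absorbs most of this (mean statistic
30.7, rejection about 0.07); the remaining terms of the ladder sit at
0.04–0.06. We evaluated two remedies and rejected both: scaling the
statistic by `(n - p)/deviance_full` (quasi-likelihood style) overcorrects
to about 0.033–0.038 because the scale shares noise with the numerator, and
choosing the dispersion by deviance matching biases `phi_hat` upward by
about 20%. The package therefore ships the plain deviance LRT and documents
that the three-way term is mildly liberal (about 0.07 at nominal 0.05) at
8 flies per cell; all other terms are within Monte-Carlo error of nominal.

## Normalization and the expression threshold

Size factors follow the median-of-ratios definition: per sample, the median
over reference genes of `count / geometric mean across samples`, using only
genes with strictly positive counts everywhere (a zero anywhere makes the
log-scale geometric mean undefined — the standard convention, which the
paper-level description leaves implicit). Note the formula's exact scale
behavior, which the tests pin down: multiplying *all* counts by a constant
leaves size factors unchanged (the ratios are scale-free) and scales the
normalized matrix; there is no extra rescaling step.

Filtering removes genes with all-zero counts, then genes below a threshold
in *every* sample — a gene expressed in even one fly is kept. The threshold
either (a) defaults to the published constant 3.486 normalized counts, or
(b) is derived from a user-supplied intergenic count table:
`derive_threshold()` computes Gaussian kernel densities (Silverman
bandwidth, common 512-point grid) of log mean normalized counts for genic
and intergenic features, locates the first point above the intergenic mode
where the genic density exceeds the intergenic one, and refines the
crossing by linearly interpolating the zero of the density difference
between the bracketing grid points (which removes the one-sided, up to
one-grid-step discretization bias of reporting a raw grid point). The
operationalization is validated against a closed form: for two equal-SD
log-normal populations the crossing is the midpoint of the two log means,
and the implementation recovers it within one grid step when the
populations genuinely overlap — the regime the method is for; when the
crossing lies many SDs into both tails, kernel density estimates there are
noise and no crossing estimator is reliable.

## CV_E, its ANOVA, and heritability

Microenvironmental plasticity of a gene is quantified per genotype x sex x
replicate cell as the coefficient of environmental variation,

    CV_E = 100 * sd / mean,

computed on normalized counts with the (n-1) SD. Cells with fewer than two
flies or non-positive means are flagged, never imputed; CV_E is exactly
scale-invariant, so normalization constants cannot leak into it.

Treating the replicate-level CV_E values as observations (three per
genotype x sex, which is what makes the genotype-by-sex term estimable),
each gene is tested with the fixed-effects ANOVA `Y = mu + S + G + G:S + e`
using Type-II sums of squares (identical to Type I/III on the balanced
design), with per-term BH-FDR across genes. Heterogeneity of variance among
individual flies within cells is additionally screened with Levene's test
and the Brown–Forsythe variant (one-way ANOVA on absolute deviations from
the cell mean or median, respectively), defaulting to the genotype x sex x
replicate cells as groups; the grouping is exposed as a parameter because
coarser screens (e.g. by genotype only) answer different questions.

Broad-sense heritability uses method-of-moments variance components from
the expected mean squares of the balanced random-effects ANOVA
(unrestricted mixed-model convention; negative solutions truncated to 0):

* expression scheme, on `log2(normalized + 1)` per fly:
  `H2 = (sG + sGR + sGS + sGRS) / (sG + sGR + sGS + sGRS + s_eps)`;
* CV_E scheme, on per-cell CV_E values with the replicate stratum as error:
  `H2 = (sG + sGS) / (sG + sGS + s_eps)`.

Two choices deserve comment. Variance components for expression are taken
on the log2 scale because components on raw NB counts conflate mean and
variance; the log transform is the standard quantitative-genetics choice,
and results on other scales will differ for strongly-expressed genes. EMS
rather than REML estimation was chosen because it is closed-form and
exactly checkable — on balanced designs with interior estimates the two
coincide, which the test suite verifies against `lme4`. Truncation keeps
`H2` in `[0, 1]` at the cost of a small upward bias near zero; recovery
simulations at the default design size put the mean estimate within 0.05
of planted values of 0.1–0.5.

## Coexpression modules and enrichment

Significant gene sets are clustered on the absolute correlation matrix
sharpened to an adjacency `A = |cor|^beta`. For each `beta` on a 24-point
grid from 0.5 to 12, communities are found by deterministic greedy
agglomerative modularity maximization (ties in the modularity gain broken
lexicographically by gene id, so results are invariant to gene order up to
relabeling), and the `beta` with the highest achieved modularity `Q` wins.
Modules are reported ordered by mean within-module connectivity,
descending. `Q` is recomputable independently via `modularity()`, and the
test suite holds the two equal to 1e-10. Exact modularity maximization is
NP-hard; greedy agglomeration was chosen over spectral or simulated
annealing variants because it is deterministic and oracle-checkable, at the
known cost that it can merge small tight modules into larger ones near the
resolution limit. Whether Pearson or Spearman correlation feeds the
adjacency is a user parameter (`pearson` default).

Module enrichment against user-supplied gene sets (GMT format) uses the
upper-tail hypergeometric test with the expressed-gene universe as
background and Bonferroni control over the number of sets. Annotation
databases themselves are deliberately out of scope — any named list of
gene sets works. The male-bias contingency check compares the fraction of
male-biased genes (mean male expression above mean female expression — the
minimal operationalization of the term) inside a focus set against the rest
of the transcriptome with Fisher's exact test.

## Covariate screens

Three line-level screens attribute individual differences to known
covariates. Wolbachia infection is tested per gene with the two-line model
`log(mu) = b0 + I` against the intercept (LRT, df 1) — deliberately
*without* a genotype term, matching the published model. Because infection
is constant within a line, this screen is anti-conservative whenever
genotype effects exist; the package documents this contract and the test
suite demonstrates the inflation rather than hiding it. Residual
heterozygosity and total rRNA level are screened by the per-gene Spearman
correlation between per-line expression SD and the covariate, with exact
permutation p-values for eight or fewer lines and the t-approximation
otherwise.

## The synthetic-data generator

`generate_design()`, `generate_truth()` and `simulate_counts()` emulate the
study conditions: a balanced 16 x 3 x 2 x 8 design (768 flies; an optional
seeded dropout emulates post-QC attrition, since real studies lose a few
samples), NB counts with gene-specific dispersion drawn uniformly from
[0.05, 1] (a deliberately wide range — from near-Poisson to strongly
overdispersed — so that downstream estimators are exercised over the whole
regime), per-gene baseline log means drawn normal(log 100, 1) to emulate a
realistic bulk expression spread, log-uniform size factors rescaled to
geometric mean 1, and sum-to-zero effect coefficients per design term so
the baseline is the grand log mean and planted log fold changes are
directly comparable to fitted contrasts. Differential CV_E is planted by
multiplying the dispersion of a random half of the genotypes (optionally in
one sex) by a configurable factor, leaving the mean model untouched, so
mean-effect and variance-effect tests stay separable by construction.

What the generator does *not* emulate: mean–dispersion trends, gene–gene
correlation beyond planted modules, library-preparation batch structure,
ERCC spike-ins, or mapping artifacts. Passing tests therefore demonstrate
the correctness and calibration of the statistical machinery under the
stated model, not robustness to violations of it.

## Numerical choices and degenerate inputs

* IRLS convergence at relative deviance change `1e-8`, at most 100
  iterations; non-convergence is flagged on the fit, not an error.
* Rank-deficient designs drop aliased columns with a warning; degrees of
  freedom always come from rank differences.
* Numerically negative LRT statistics (convergence noise) are clamped to 0.
* The dispersion search runs on `log(phi)` in `[1e-6, 25]` with tolerance
  `1e-2`; estimates below `1e-4` are reported as exactly 0.
* All-zero genes raise a degenerate-gene error in single-gene functions and
  yield flagged NA rows in table-level functions.
* All generators draw through an internal seed guard, so identical
  arguments and seed give bit-identical output without disturbing the
  caller's RNG stream.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the pipeline at the full
768-sample design with 200–2000 genes per check (type-I calibration uses
2000 null genes; recovery checks use 500; CV_E power uses 200 planted plus
200 null), and smaller 4 x 2 x 2 x 4 designs for unit-level properties.
These sizes were chosen so the complete validation runs comfortably on a
laptop-class single core while keeping Monte-Carlo error well below the
asserted tolerances.

## Known limitations

* Per-gene dispersion without shrinkage is noisier than trend-shrunken
  estimators for very low-count genes; the filtering step is assumed to
  have removed those.
* The three-way interaction LRT is mildly liberal at 8 flies per cell (see
  the calibration section).
* EMS variance components assume balance; modest imbalance falls back to
  average cell sizes with a warning, and badly unbalanced designs deserve a
  REML treatment outside this package's scope.
* The greedy modularity optimizer is deterministic but not exact; reported
  `Q` is a lower bound on the achievable modularity.
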