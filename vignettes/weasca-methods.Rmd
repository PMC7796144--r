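---
title: "Methods: weighted-effect ASCA for unbalanced multifactorial designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted-effect ASCA for unbalanced multifactorial designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weasca)
```

## The model

A multifactorial experiment measures an $n \times m$ response matrix $X$
(observations in rows; features such as wavenumbers in columns) under $F$
categorical factors. ASCA-type methods decompose $X$ additively,

$$X = M_0 + \sum_f \mathrm{Con}_f + \hat{E},$$

with one effect matrix $\mathrm{Con}_f$ per modelled term $f$ (main effects
and two-way interactions), each constant within the design cells of its
term, and each summarized afterwards by its own PCA. The decomposition is
estimated through a multivariate general linear model: a coded design
matrix $D$ ($n \times p$) and a parameter matrix $\hat\beta = (D^TD)^{-1}D^TX$,
with $\mathrm{Con}_f = D_{/f}\,\hat\beta$, where $D_{/f}$ keeps only the
columns of term $f$ (all other columns, including the intercept, zeroed).
The additive model assumes effects enter linearly and the residual is
exchangeable across observations — the assumption the permutation test
relies on.

## Coding schemes and why they matter

A factor with $\alpha$ levels occupies $\alpha - 1$ design columns; an
interaction of $\alpha \times \beta$ levels occupies
$(\alpha-1)(\beta-1)$ columns. Identifiability therefore never depends on
the scheme; what changes is what the parameters *mean*:

- **dummy** (0/1 reference coding): parameters are deviations from the
  reference (last) level.
- **deviation** (sum-to-zero): the reference level is coded $-1$;
  parameters are deviations from the unweighted grand mean of level means.
- **weighted-effect**: the reference level of the column for level $q$ is
  coded $-n_q/n_{\mathrm{ref}}$, with the interaction column for the
  non-reference pair $(p, q)$ carrying $+1$ in cell $(p,q)$,
  $-n_{p,q}/n_{p,\beta}$ in $(p,\beta)$, $-n_{p,q}/n_{\alpha,q}$ in
  $(\alpha,q)$ and $+n_{p,q}/n_{\alpha,\beta}$ in $(\alpha,\beta)$.

Every weighted-effect column sums to zero over the *observations*, not
merely over the levels. Consequences, all exercised by the test suite:
effect columns stay orthogonal to the intercept under arbitrary unbalance,
the fitted intercept row equals the column means of $X$, every effect
matrix is column-centred, and level effects are deviations from the
observation-weighted mean. On a balanced design all cell-count ratios equal
one and weighted-effect coding collapses to deviation coding; both then
agree with the classical cell-mean estimator.

```{r coding-example}
fx <- worked_example_fixture("unbalanced7")   # 2 x 3 design, one duplicated cell
build_design_matrix(fx$design, model_spec("A + B + A:B", "weighted"))$values
```

The reference level is the *last* level in the declared order; level order
defaults to first appearance in the design table and can be overridden via
the `levels` argument of `factor_design()`. Count ratios are formed by one
floating division of two integer counts, so fractions like $-3/4$ are
represented exactly as R doubles.

The classical estimator (`classical_asca_decompose()`) builds contributions
directly from observation means — level mean minus grand mean for a main
effect; cell mean minus both level means plus grand mean for an interaction
— and is applied as-is to unbalanced designs, where its effect matrices are
generally non-orthogonal. It is retained as the comparison baseline, not as
a recommended estimator.

## Variance partitioning

`type3_percent_variance()` measures each term after all others: the model
is refitted without the term's columns and

$$SS(f) = \lVert\hat E_f\rVert^2 - \lVert\hat E\rVert^2, \qquad
\%\mathrm{Var}_f = \frac{SS(f)}{\lVert X - M_0\rVert^2} \times 100 .$$

Three deliberate choices:

- **Reduced models keep every other term**, including an interaction whose
  main effect was dropped. The reduced fit simply omits the term's columns
  from the full coded matrix, which is equivalent to recoding the reduced
  term list and keeps the procedure well-defined for any term.
- **The denominator is always $\lVert X - M_0\rVert^2$ with the
  column-mean $M_0$**, for every coding scheme, so percentages are
  comparable across schemes. (Under deviation coding on unbalanced data
  the *fitted* intercept differs from the column means; the decomposition
  reports the fitted intercept as its `M0`, the partition uses column
  means.)
- Classical ASCA is summarized by the naive norm ratio
  $\lVert \mathrm{Con}_f \rVert^2 / \lVert X - M_0\rVert^2$
  (`naive_percent_variance()`), which is what makes its percentages exceed
  100% in aggregate on unbalanced designs; both partitions are exposed.

On balanced designs type III, sequential (type I) and naive partitions
coincide and the percentages, residual included, sum to 100. A response
with identical rows has zero corrected total; percentages are then reported
as 0 rather than 0/0.

## Permutation tests

For term $f$, the statistic is the sum of squares of the first $l$ score
columns of the term's PCA sub-model; with the default `l = "all"` this is
exactly $\lVert \mathrm{Con}_f\rVert^2$. Whole rows of $X$ are permuted
against the fixed design $N$ times, the decomposition is recomputed under
the same coding, and

$$p(f) = \frac{\#\{SS_r(f) \ge SS(f)\}}{N},$$

with the observed data *not* counted among the permutations, so $p = 0$ is
attainable. Permutation is unrestricted (no within-stratum schemes).
`permutation_tests()` runs one independent stream per term, offsetting the
seed by the term's position. The design matrix is QR-factored once and
reused across permutations, so a test costs $N$ triangular solves rather
than $N$ full refits; the number of leading components $l$ is a logged
configuration knob, with "all components" as the default since restricting
$l$ discards effect variance without a principled cutoff.

## PCA sub-models and augmented scores

`fit_effect_submodel()` takes the SVD of one effect matrix *without
re-centring*: weighted-effect matrices are column-centred by construction,
and deviation-coded effect matrices on unbalanced data are deliberately
left as estimated rather than silently recentred. Loadings are orthonormal;
each loading's largest-magnitude entry is made positive so scores are
reproducible across platforms; components beyond the matrix rank are
flagged and reported with exactly zero variance. A two-level factor yields
a rank-one effect matrix — its PC1 explains 100% of the effect's variance —
and an $\alpha$-level factor at most $\alpha - 1$ nonzero components.

Residual-augmented scores, $(\mathrm{Con}_f + \hat E)\,P_f$, put one point
per observation on the effect's component axes; per-level means recover the
level scores and per-level covariances sketch the within-level scatter. The
plotting layer (`plot_effect_scores()`) draws these with 2-standard-
deviation ellipses — the ellipse radius is a display default, not a
confidence statement. Reporting defaults to $k = 2$ components; the
permutation statistic always has access to the full rank internally.

## Effect removal and cross-validated classification

`remove_effect()` subtracts one fitted term from the response,
$X_{\mathrm{corr}} = X - \mathrm{Con}_f$; refitting the same model on
$X_{\mathrm{corr}}$ leaves the removed term with essentially zero variance.
`crossvalidate()` embeds this in leave-one-group-out classification:

- Folds are the levels of a grouping factor (e.g. the individual). The
  nuisance decomposition is refitted on the training rows of every fold —
  never on the full data — and only the nuisance term is subtracted.
- **The nuisance model should contain the class factor as well** when
  classes are unevenly distributed over groups; otherwise the nuisance
  term absorbs part of the class signal and removal discards it.
- **Held-out rows are never corrected.** A new group's nuisance effect is
  unobservable by construction, so the test set is predicted raw by both
  the corrected and the uncorrected arm.
- "Mean sensitivity" is the unweighted mean of per-class recalls over the
  classes present in a fold's test set; the band is the standard deviation
  of fold sensitivities. A pooled-confusion alternative is available
  (`pooled = TRUE`).
- Classifiers: PCA-LDA (discriminant on leading training-fold principal
  components) and PLS-DA (discriminant on supervised latent variables
  fitted to one-hot class targets; latent variables via `mixOmics::pls`,
  prediction by the discriminant on latent scores, not by the regression
  output). The component grid defaults to 1–20 and is truncated to the
  training-fold rank with a warning. Plain LDA is the default; a ridged
  pooled-covariance discriminant backs it up when within-class scatter is
  degenerate (`ridge` sets the fraction of the mean diagonal added).

All classifier statistics — centering, principal directions, latent
variables, discriminants — are computed from training rows only; the test
suite asserts that garbling test-row features changes no training-side
quantity.

## The synthetic-data generator

`simulate_dataset()` emulates the *structure* of spectral factorial data:
a smooth baseline (sum of Gaussian peaks over the feature axis), one smooth
random profile per design-matrix column of each modelled term, i.i.d.
Gaussian noise, and arbitrary per-cell counts. Ground-truth effect matrices
are built in the column space of the weighted-effect coding of the realized
design, so they satisfy the weighted zero-sum constraint exactly and
recovery tests measure estimator error, not parameterization mismatch. At
zero noise the weighted decomposition reproduces the truth to machine
precision. Defaults: m = 200 features, 5 peaks per profile, unit noise —
small enough for seconds-scale tests while keeping the smooth, correlated
feature structure of spectra.

What it does *not* emulate: baseline drifts, cosmic spikes, detector
artefacts, or any correlation structure *between* the effects of different
individuals. Each individual's effect profile is drawn independently. This
matters for interpreting the cross-validation experiments: with i.i.d.
per-individual profiles, a held-out individual's offset is statistically
unpredictable from the training set, so effect-removal preprocessing
raises the *peak* mean sensitivity of the corrected arm (the training-set
class structure is cleaner at low component counts) but does **not**
reliably narrow the across-fold dispersion — the corrected classifier has
never seen any individual-effect direction and cannot discount the test
group's offset, while an uncorrected classifier partially whitens such
directions through its within-class scatter. Conversely, when individual
effects share a few common spectral modes, a discriminant given enough
components learns to ignore them and removal adds nothing. Real
individual effects live between these extremes; passing simulation tests
therefore demonstrate the mechanics and the peak-sensitivity benefit, not
a universal variance reduction on real data.

## Numerical choices

- Least squares via QR decomposition; the normal-equation formula is the
  contract, not the algorithm. Rank deficiency raises an "aliased design"
  error; an explicit `allow_deficient = TRUE` switches to the minimum-norm
  SVD solution.
- Type III sums of squares are clamped at zero against floating round-off
  (they are non-negative in exact arithmetic).
- Sub-model rank uses the SVD tolerance
  $\max(n, m)\,\varepsilon\,d_1$; singular values below it are reported as
  exactly zero variance.
- Reconstruction, orthogonality and centring identities are asserted in
  tests at 1e-8 (relative) and column zero-sums at 1e-12 — the scales the
  algebra guarantees for well-conditioned doubles.
- Degenerate inputs: identical-row responses give zero effect percentages
  and permutation p-values of exactly 1; empty modelled cells, single-level
  factors, duplicate observation ids and non-numeric response cells are
  rejected with named errors.

## Problem sizes used by the test suite

Unit and property tests run on designs of 6–60 observations and 3–30
features with randomized unbalance. The permutation calibration uses 200
replicate null data sets at N = 500 permutations plus an exhaustive
enumeration of all 720 row permutations at n = 6; the cross-validation
experiment uses 20 groups × ~10 spectra at 40 features over 25 replicates;
the I/O smoke test decomposes one 485 × 696 matrix under a four-factor
model. These sizes keep the full suite in the tens of seconds while leaving
every scientific property at full strength.

## Known limitations

Continuous covariates (ANCOVA), nested designs, interactions beyond two
factors, response scaling variants, missing-cell imputation and
random-effect or multilevel extensions are out of scope. Classical ASCA's
naive percentages are reported for comparison only. The generator's
independence assumptions, and their consequences for cross-validation
claims, are described above.
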