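---
title: "Models and methods behind the admixlat pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the admixlat pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixlat)
```

admixlat implements an end-to-end analysis of three-way admixture in
Latin American cohorts: marker selection, supervised ancestry estimation
with uncertainty, spatial statistics, phenotype regression with
measurement-error correction, a self-perception bias analysis, facial
morphometrics and a wealth index. This vignette explains the models, the
defaults and the numerical choices, and states what the synthetic-data
generator does and does not emulate.

## The admixture likelihood and its EM maximizer

A genotype is the count of a designated reference allele at a biallelic
marker, so $g_{ij} \in \{0,1,2\}$. Conditional on the individual's
ancestry proportions $q_i$ on the $K$-simplex and fixed parental allele
frequencies $f_{jk}$,

$$g_{ij} \sim \mathrm{Binomial}\!\left(2,\; p_{ij}\right), \qquad
  p_{ij} = \sum_k q_{ik} f_{jk}.$$

`estimate_ancestry()` maximizes the per-individual log-likelihood with
the multiplicative EM update

$$q_k \leftarrow q_k \cdot \frac{1}{2M'} \sum_j \left[
   \frac{g_j f_{jk}}{p_j} + \frac{(2-g_j)(1-f_{jk})}{1-p_j} \right],$$

$M'$ the number of non-missing markers. This is the supervised special
case of the standard admixture model: with $f$ fixed the problem is
concave in $q$, the update preserves the simplex, and the likelihood is
non-decreasing at every step (the implementation asserts this at run
time). Initialization is uniform $q = (1/K, \dots, 1/K)$ and affects only
iteration count; convergence is declared when the log-likelihood gain
drops below $10^{-7}$, with an iteration cap of 5000 — EM approaches
boundary optima (individuals with $q_k \approx 0$) along slowly
contracting paths, which is why the cap is generous.

Numerical choices: panel frequencies are clamped to
$[10^{-6}, 1-10^{-6}]$ before evaluation. AIM panels deliberately include
markers monomorphic in one parental population; without clamping those
produce $\log 0$ at the simplex corners the panel is designed to resolve.
Missing genotypes contribute nothing; an individual with no observed
genotypes is returned as flagged `NA`. If all populations share identical
frequencies the likelihood is flat — the estimate stays uniform and the
`identifiable` flag is set.

A 0.01-step simplex grid search (`grid_search_ancestry()`) is kept in the
package purely as an independent check; the test suite requires the EM
optimum to agree with the exhaustive grid maximum to within grid
resolution.

**Bootstrap.** `bootstrap_se()` resamples markers with replacement
(B = 200 by default) and reports the per-component standard deviation of
the re-estimates. Markers are the resampling unit because parental
frequencies are treated as known and individuals are estimated
independently; a simple (non-block) bootstrap is appropriate since AIM
panels are built from near-independent markers. The bootstrap EM uses a
slightly looser tolerance ($10^{-5}$) than the point estimates: the
Monte-Carlo spread across replicates is orders of magnitude larger than
the optimizer residual, so tighter tolerance buys nothing.

## Marker selection

`select_aims()` ranks candidates by
$\max(|f_{EUR}-f_{NAM}|,\, |f_{EUR}-f_{AFR}|)$ and then, within the top
`top_fraction` of the ranking, keeps the `n_select` markers with smallest
Native American expected heterozygosity $2f(1-f)$. Two decisions were
genuinely open:

* the size of the "highest-differential" pool is not a published
  constant, so it is exposed as `top_fraction` (default 0.2 — permissive
  enough that the heterozygosity filter has real work to do, strict
  enough that uninformative markers cannot slip in);
* the two EUR-involving differentials could be combined by max or sum;
  max is the default and sum is available via `combine = "sum"`.

Ties break lexicographically by marker id, making selection fully
deterministic. `panel_accuracy_curve()` quantifies the diminishing return
of panel size by re-estimating ancestry with panels selected at each
size and correlating against the generator's truth.

## Spatial analyses

Locations are birthplaces; distances are haversine on WGS84 degrees
(country-scale extents make planar distances materially wrong).
`morans_i()` uses row-standardized weights, by default inverse
great-circle distance with k-nearest-neighbour available; the choice of
"standard autocorrelation" weights was open and the default is the most
common explicit one. Significance comes from `permutation_test_spatial()`:
individuals are reassigned to birthplaces uniformly at random with
per-location sample sizes fixed, location means recomputed each time, and
$p = (1 + \#\{|I_b| \ge |I_{obs}|\}) / (B+1)$ — the add-one estimator
never reports zero. The same scheme drives the canonical-correlation
test, where the ancestry block uses $K-1$ columns (the simplex constraint
makes the last redundant) against a full bivariate polynomial in
standardized (lat, lon) up to degree 3 by default; degree 4 is available
but adds nothing on smooth gradients, matching the observation that
cubic terms suffice for curved gradients. Whether individuals or whole
locations should be permuted was ambiguous; permuting individuals'
birthplaces matches the Moran scheme and is what both tests use.
`spatial_null_calibration()` exists so the exactness claim is checkable:
under a structureless generator the rejection rate at $\alpha$ must sit
inside the binomial interval around $\alpha$.

**Kriging.** `krige_surface()` fits an empirical semivariogram (12
equal-width bins to half the maximum distance) by weighted least squares
with Cressie weights $N_h/\gamma^2$, spherical model by default
(exponential optional), nugget fixed at 0 so the surface honours the
observed location means exactly. Ordinary kriging solves one augmented
system factored once for all grid cells (default 50×50 over the data
bounding box); predictions are clipped to [0, 1] since they are
proportions. A degenerate fit (near-constant field) falls back to
inverse-distance weighting with a warning rather than failing.

## Phenotype regressions and measurement error

`fit_phenotype_model()` is OLS for continuous and ordinal traits (ordinal
codes entered as integers; `probit_check = TRUE` fits the ordered-probit
cross-check, which agrees in direction whenever a latent continuous trait
underlies the categories) and ML logistic for binary traits, where the
reported $R^2$ is McFadden's and labelled as such. Native American
ancestry is the baseline: $q_{EUR}$ and $q_{AFR}$ enter as predictors.
`delta_r2()` refits full and covariate-only models on the identical
complete-case rows — it errors rather than silently comparing different
samples — and reports the non-negative $R^2$ increment.

`eiv_adjust()` corrects for the fact that $\hat q$ is an estimate. The
method-of-moments estimator subtracts the average measurement-error
variance (diagonal, from the bootstrap $se^2$) from the ancestry block of
the predictor covariance: $\beta = (S_{xx} - \Lambda)^{-1} S_{xy}$. In
the scalar case this is exactly the classical attenuation correction
$\beta_{naive}/\lambda$ with $\lambda = \sigma^2_x/(\sigma^2_x +
\sigma^2_e)$, which the tests verify against the closed form. Averaging
heteroscedastic per-individual $se^2$ into one $\Lambda$ is the standard
moment treatment. A full-likelihood EIV fit was considered and rejected:
the moment correction is transparent, fast, and reproduces the expected
modest (few-percent) de-attenuation when $se(q)$ is a few percent.
If $S_{xx} - \Lambda$ loses positive-definiteness (small samples, large
errors) the function stops and suggests `shrinkage`, which scales the
subtraction, rather than silently returning a non-sensical fit. SEs for
both naive and corrected coefficients are sandwich estimates with the
respective residuals.

`trait_scan()` applies a Bonferroni threshold `alpha_family / n_traits`;
with 18 traits and family $\alpha = 0.018$ that is the conventional
$10^{-3}$ per-test bar, and the 630-distance morphometric scan at family
$\alpha \approx 6 \times 10^{-4}$ lands on $10^{-6}$.

## Morphometrics

`gpa()` performs full generalized Procrustes analysis: configurations are
centred, scaled to unit centroid size, and iteratively rotated onto the
evolving mean shape until it stabilizes; rotations are proper (no
reflections) because faces are chirality-bearing. Partial Procrustes
(no scaling) was the open alternative; full Procrustes is the default
here and centroid sizes are returned separately in original units so no
information is lost. `shape_pca()` projects the aligned coordinates into
the tangent space at the mean shape before PCA — the standard
linearization; PCA directly on Procrustes coordinates differs negligibly
at facial-variation scales but the tangent projection is the
theoretically clean choice. PC loading signs are fixed by orienting each
loading's largest element positive, so scores are reproducible across
runs and platforms. `interlandmark_scan()` regresses all $L(L-1)/2$
distances (630 at $L = 36$) on ancestry and covariates in one
multi-response least-squares pass.

## Self-perception bias

Bands are 20% brackets: band $b$ covers $[(b-1)/5,\ b/5]$, treated as
closed at both ends — a boundary value is consistent with either adjacent
band, so zero bias is the conservative reading. The bias is
$\Delta = 0$ inside the band, otherwise (nearest boundary − genetic
value), positive when self-perception overshoots. The alternative
"band midpoint minus genetic value" definition is implemented
(`perception_bias_midpoint()`) because the distance and midpoint readings
cannot be distinguished from the published descriptions alone; the
distance form is the default throughout and a single flag switches.

`reference_pyramid()` builds the theoretical picture of accurate
self-perception: per band, a beta distribution with median at the band
centre and 75% of its mass inside the band, solved by Nelder-Mead on
$(\log\alpha, \log\beta)$ to squared-residual $10^{-10}$ (both
constraints are smooth and monotone in the parameters; random restarts
guard the rare stall). The tests require both constraints to hold within
$10^{-4}$.

## Wealth index

`polychoric_corr()` is the two-step estimator: thresholds from marginal
normal quantiles, then a 1-D likelihood maximization for $\rho$ over
$(-1, 1)$, with bivariate-normal rectangle probabilities obtained by
quadrature of the conditional-normal identity. Two-step rather than full
ML because at survey sample sizes the efficiency loss is negligible and
the estimator is fast and stable. Empty cells are left to the likelihood
(no continuity fudge). `wealth_index()` builds the per-country polychoric
matrix (eigenvalue-clipped to PSD if pairwise estimation leaves it
slightly indefinite, with a warning), takes the first eigenvector as item
weights on standardized codes, orients the score to correlate positively
with an anchor item (bathrooms by default), and converts to within-country
deciles with average-rank ties. Item standardization and the tie rule
were unspecified upstream; both choices are stated here and fixed.

## The synthetic-cohort generator

`simulate_cohort()` produces data with the structure the analyses assume:

* **Parental frequencies** follow the Balding–Nichols model — marker-wise
  ancestral frequency $p \sim U(0.1, 0.9)$, population frequency
  $\mathrm{Beta}\!\left(p\frac{1-F}{F},\ (1-p)\frac{1-F}{F}\right)$ with
  per-population drift $F$ (default 0.15) — plus a configurable fraction
  of near-diagnostic markers (default 20%), emulating an
  information-enriched AIM panel.
* **Ancestry** is Dirichlet per individual about a location mean: the
  country's mean ancestry profile (five strata whose AFR/EUR/NAM means
  follow the characteristic profiles of Brazil, Chile, Colombia, México
  and Perú) shifted on the log scale by a linear gradient in standardized
  latitude (default $(-0.5, -1.0, 1.2)$ for AFR/EUR/NAM — Native American
  ancestry rising and African/European falling toward the high-altitude
  end, the direction real cohorts show). Dirichlet concentration
  (default 12) sets within-location dispersion and shrinks with census
  size, so big cities are more heterogeneous — the feature the
  sd-vs-census analysis targets.
* **Genotypes** are Binomial(2, $q^\top f$) — exactly the estimator's
  model; missingness is injected uniformly at a configurable rate
  (default 0).
* **Phenotypes** are linear in $(q_{EUR}, q_{AFR})$ plus covariates and
  Gaussian noise; ordinal traits threshold a latent variable, binary
  traits are logistic. Default effect sizes put pigmentation strongly and
  anthropometrics weakly under ancestry control, the contrast real
  studies report.
* **Self-perception** bands the value $q_k + w \cdot s_k \cdot
  \text{mel}_z + \varepsilon$ clipped to [0, 1], with melanin pushing
  AFR/NAM perception up and EUR down ($s_k = +1, -1, +1$); boundary ties
  go to the lower band, consistent with the closed-interval convention.
  Default $w = 0.12$, $\sigma_\varepsilon = 0.06$.
* **Assets and landmarks**: six ordinal asset items loaded on one latent
  wealth factor; 36 3D landmarks as a template plus an ancestry-linked
  deformation axis and individual noise, wrapped in random similarity
  transforms (arbitrary camera units).

All randomness flows from the single integer seed in the configuration
through a scoped-RNG helper, so cohorts are byte-reproducible and the
caller's RNG state is untouched.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: linkage disequilibrium between markers
(AIM panels are built near-independent, but real residual LD slightly
correlates bootstrap draws), uncertainty in the parental frequencies
themselves, assortative mating and family structure, non-Gaussian
phenotype noise, informative missingness, and geocoding error in
birthplaces. Country mean-ancestry profiles are realistic medians, but
the within-country distributions are free parameters of the generator,
not calibrated claims about any real cohort.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run the estimator checks at
200 individuals × 1000 markers (where the grid-search comparison is
still exhaustive at step 0.01), the panel-size curve at 500 × 800
candidates, the spatial calibration at 500 null replicates × 199
permutations with 1000 individuals over 100 locations, and the
errors-in-variables cohort checks at 1500 × 45 markers. These sizes give
Monte-Carlo error comfortably below each acceptance tolerance while
keeping a full run in the low minutes on a laptop core.

## Known limitations

* The EM treats parental frequencies as known; panels estimated from
  small reference samples propagate no reference uncertainty into the
  bootstrap SEs.
* The EIV correction is first-order in the error variance; with
  bootstrap SEs above ~0.1 (very small panels) the corrected covariance
  can lose definiteness, which the function reports rather than papers
  over.
* Ordinary kriging assumes second-order stationarity of location means;
  strong trends should be removed or acknowledged (the planar-recovery
  test shows small but non-zero edge bias).
* The polychoric quadrature targets two-digit accuracy in extreme-cell
  probabilities; for tables with near-empty extreme cells the likelihood
  is flat and $\hat\rho$ inherits that uncertainty.
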