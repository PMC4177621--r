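# admixlat

Tools for three-way (African / European / Native American) admixture
analysis in Latin American cohorts: estimating individual ancestry
proportions from a small panel of ancestry-informative markers (AIMs),
testing the spatial structure of ancestry, regressing physical-appearance
phenotypes on ancestry with measurement-error correction, and quantifying
how self-perceived ancestry deviates from the genetic estimates. A
synthetic-cohort generator reproduces the statistical structure of such
studies so the entire pipeline is testable without access to restricted
cohort data.

The package is aimed at population-genetics and biosocial researchers
working with admixed cohorts where genotyping budgets favour small AIM
panels and where questionnaire data (self-perceived ancestry bands,
socioeconomic items) accompany the genetics.

## The statistical core

**Supervised ancestry estimation.** With parental allele frequencies
f<sub>jk</sub> held fixed, the genotype g<sub>ij</sub> ∈ {0,1,2} of
individual i at biallelic marker j is Binomial(2, p<sub>ij</sub>) with
p<sub>ij</sub> = Σ<sub>k</sub> q<sub>ik</sub> f<sub>jk</sub>. The
log-likelihood

log L<sub>i</sub>(q) = Σ<sub>j</sub> [ g<sub>ij</sub> log p<sub>ij</sub> + (2 − g<sub>ij</sub>) log(1 − p<sub>ij</sub>) ]

is maximized over the K-simplex by multiplicative EM updates; the problem
is concave in q, the update is monotone in the likelihood, and bootstrap
standard errors come from resampling markers (B = 200 by default).

**AIM selection.** Candidate markers are ranked by the larger of
|f<sub>EUR</sub> − f<sub>NAM</sub>| and |f<sub>EUR</sub> − f<sub>AFR</sub>|;
within the top fraction of that ranking the panel takes the markers with
lowest Native American expected heterozygosity 2f(1 − f), insulating the
estimates from allele-frequency variation among Native American groups.

**Spatial structure.** Moran's I (row-standardized inverse great-circle
distance weights) and canonical correlations between ancestry and a cubic
polynomial in (lat, lon) are tested by permuting individuals across
birthplaces while preserving per-location sample sizes; surfaces are drawn
by ordinary kriging of location mean ancestry with a WLS-fitted spherical
semivariogram (exact at data points when the nugget is zero).

**Phenotype regressions.** Each trait is regressed on (q<sub>EUR</sub>,
q<sub>AFR</sub>) — Native American ancestry as baseline — plus age, sex,
country, education and wealth; ΔR² (full minus covariate-only model) is
the variance attributable to ancestry. Because q̂ carries estimation
error, a method-of-moments errors-in-variables correction subtracts the
mean bootstrap error variance from the predictor covariance before
solving, undoing the attenuation of the ancestry coefficients.

**Self-perception bias.** Participants place each continental ancestry in
one of five 20% bands. The bias Δ is zero when the genetic proportion
falls inside the chosen band and otherwise the signed distance from the
nearest band boundary; regressions of Δ on ancestry, phenotypes and
social covariates identify what drives over- and under-estimation. A
beta-distribution "reference pyramid" gives the theoretical picture of
accurate self-perception (median at each band centre, 75% of mass within
the band).

Also included: generalized Procrustes analysis of 3D facial landmarks
with tangent-space shape PCs and the 630-distance inter-landmark scan,
and a polychoric principal-component wealth index with within-country
deciles.

## Worked example

```r
library(admixlat)

cfg    <- sim_config(n_individuals = 500, n_markers = 30, seed = 42)
cohort <- simulate_cohort(cfg)

aligned <- align_panel(cohort$genotypes, cohort$parental_freqs)
est     <- estimate_ancestry(aligned$genotypes, aligned$panel)
est
#> ancestry_estimates: 500 individuals, K = 3 (AFR/EUR/NAM)
#>   mean q: AFR=0.070 EUR=0.585 NAM=0.345

se <- bootstrap_se(aligned$genotypes, aligned$panel, B = 200, seed = 42)
round(colMeans(se), 3)
#>   AFR   EUR   NAM
#> 0.093 0.124 0.114

design <- ancestry_design(est, cohort$pheno_geo, se = se)
trait_scan(design, c("melanin_index", "height", "eye_color"),
           alpha_family = 0.003)[, c("trait", "coef_EUR", "p_EUR",
                                     "delta_r2", "sig_EUR")]
#>           trait coef_EUR    p_EUR delta_r2 sig_EUR
#> 1 melanin_index    -7.21 4.09e-24   0.1964    TRUE
#> 2        height     6.00 4.24e-08   0.0335    TRUE
#> 3     eye_color    -1.91 2.06e-18   0.1363    TRUE
```

The mean q values show the cohort's admixture profile. With only 30
markers the bootstrap SEs sit around 0.09–0.12, which is why the
regression layer carries the errors-in-variables option. The scan says
skin pigmentation is strongly ancestry-driven (ΔR² ≈ 0.20: a fifth of
melanin-index variance is explained by ancestry beyond the covariates),
height much less so — the generator builds in exactly this contrast, and
the fitted European-ancestry coefficients (−7.2 pigmentation units, +6 cm)
recover it with the expected attenuation from noisy q̂.

Self-perception bias for the same cohort:

```r
rec <- bias_records(est, cohort$perception)
summary(rec$bias_EUR)
#>    Min.  1st Qu.  Median    Mean  3rd Qu.    Max.
#> -0.4293   0.0000  0.0000  0.0008   0.0000   0.3980
```

Most individuals' bands contain their genetic estimate (Δ = 0); the tails
are the individuals whose self-perception over- or under-shoots.

A command-line front end over the same functions lives at
`inst/cli/admixlat.R`:

```sh
Rscript inst/cli/admixlat.R simulate --seed 5 --out-dir cohort
Rscript inst/cli/admixlat.R ancestry --genotypes cohort/genotypes.vcf \
    --panel cohort/parental_freqs.csv --bootstrap 200 --seed 2 --out-dir anc
Rscript inst/cli/admixlat.R spatial --estimates anc/ancestry.csv \
    --meta cohort/pheno_geo.csv --perms 999 --out-dir spatial
```

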