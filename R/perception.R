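# perception: the banded self-perceived-ancestry bias statistic, its
# regression on ancestry/phenotypes/covariates, and the reference beta
# "pyramid" simulation for the theoretical case of accurate self-perception.
#
# Self-perception of each continental ancestry is recorded on a five-point
# scale of 20% bands: 1) 0-20%, 2) 20-40%, 3) 40-60%, 4) 60-80%,
# 5) 80-100%. Bias (delta) is self-perception minus genetic ancestry: zero
# when the genetic proportion falls inside the chosen band, otherwise the
# signed distance from the closest band boundary to the genetic value.

#' Self-perception band interval
#'
#' @param band integer 1-5
#' @return numeric `c(lo, hi)` = `((band-1)*0.2, band*0.2)`; intervals are
#'   treated as closed at both ends for the containment test, so boundary
#'   values yield zero bias
#' @export
band_interval <- function(band) {
  if (!all(band %in% 1:5)) stop_config("band must be in 1..5")
  cbind(lo = (band - 1) * 0.2, hi = band * 0.2)
}

#' Self-perception bias
#'
#' delta = 0 if the genetic proportion lies in the band's closed interval;
#' otherwise the signed distance from the closest band boundary:
#' `hi - q` (negative) when q exceeds the band, `lo - q` (positive) when q
#' falls below it. Vectorized over individuals.
#'
#' @param genetic_q genetic ancestry proportion(s) in \[0, 1\]
#' @param band self-perception band(s) 1-5
#' @return signed bias in \[-1, 1\]
#' @export
perception_bias <- function(genetic_q, band) {
  if (any(genetic_q < 0 | genetic_q > 1, na.rm = TRUE))
    stop_config("genetic_q must lie in [0, 1]")
  iv <- band_interval(band)
  unname(ifelse(genetic_q > iv[, "hi"], iv[, "hi"] - genetic_q,
                ifelse(genetic_q < iv[, "lo"], iv[, "lo"] - genetic_q, 0)))
}

#' Bias using band midpoints (alternative definition)
#'
#' Band midpoint minus the genetic proportion; provided for sensitivity
#' analysis against the distance-to-boundary default.
#'
#' @inheritParams perception_bias
#' @export
perception_bias_midpoint <- function(genetic_q, band) {
  if (any(genetic_q < 0 | genetic_q > 1, na.rm = TRUE))
    stop_config("genetic_q must lie in [0, 1]")
  (band - 0.5) * 0.2 - genetic_q
}

#' Bias records for a cohort
#'
#' @param estimates `ancestry_estimates` or N x K matrix
#' @param perception data.frame with `sample_id` and `band_<pop>` columns
#' @param method `"boundary"` (distance to closest band boundary, default)
#'   or `"midpoint"`
#' @return data.frame: sample_id, then per component band, lo, hi, q and
#'   bias columns
#' @export
bias_records <- function(estimates, perception,
                         method = c("boundary", "midpoint")) {
  method <- match.arg(method)
  q <- if (inherits(estimates, "ancestry_estimates")) estimates$q else as.matrix(estimates)
  out <- data.frame(sample_id = perception$sample_id)
  fn <- if (method == "boundary") perception_bias else perception_bias_midpoint
  for (k in colnames(q)) {
    bc <- paste0("band_", k)
    if (!bc %in% names(perception)) next
    b <- perception[[bc]]
    iv <- band_interval(b)
    out[[bc]] <- b
    out[[paste0("q_", k)]] <- q[, k]
    out[[paste0("bias_", k)]] <- fn(q[, k], b)
  }
  out
}

#' Regression of self-perception bias on ancestry, phenotypes, covariates
#'
#' One linear fit per continental bias. Positive coefficients mean the
#' predictor pushes self-perception above the genetic estimate
#' (overestimation), negative below (underestimation). If self-perception
#' were accurate, every coefficient would be non-significant.
#'
#' @param records output of [bias_records()]
#' @param design an [ancestry_design()] whose data also carries the
#'   phenotype predictors to include
#' @param phenotypes character vector of phenotype columns to add to the
#'   ancestry + covariate predictors
#' @return named list of `regression_fit`s, one per continent found
#' @export
fit_bias_model <- function(records, design, phenotypes = character()) {
  comps <- sub("^bias_", "", grep("^bias_", names(records), value = TRUE))
  out <- list()
  for (k in comps) {
    d2 <- design
    d2$data[[paste0("bias_", k)]] <- records[[paste0("bias_", k)]]
    out[[k]] <- fit_phenotype_model(d2, paste0("bias_", k),
                                    family = "linear",
                                    extra_covariates = phenotypes)
  }
  out
}

#' Correlation between self-perception band and genetic ancestry
#'
#' @param bands integer vector of bands (1-5)
#' @param genetic_q matching genetic proportions
#' @param method `"pearson"` (default) or `"spearman"`
#' @return list: `r`, `p`, `flagged` (TRUE when the bands are constant and
#'   the correlation is undefined)
#' @export
band_correlation <- function(bands, genetic_q,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (stats::var(bands) == 0)
    return(list(r = NA_real_, p = NA_real_, flagged = TRUE))
  ct <- suppressWarnings(stats::cor.test(bands, genetic_q, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, flagged = FALSE)
}

# beta with median m and mass `coverage` in [m-0.1, m+0.1]: 2-D root find
# on (log a, log b); constraints are smooth and monotone in the parameters
.calibrate_beta <- function(centre, coverage, tol = 1e-10) {
  lo <- max(centre - 0.1, 0); hi <- min(centre + 0.1, 1)
  resid <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    c(stats::qbeta(0.5, a, b) - centre,
      (stats::pbeta(hi, a, b) - stats::pbeta(lo, a, b)) - coverage)
  }
  obj <- function(par) sum(resid(par)^2)
  # moment-flavoured start: mean ~ centre, spread wide enough to miss mass
  s0 <- 8
  par <- log(c(centre * s0 + 0.5, (1 - centre) * s0 + 0.5))
  for (attempt in 1:5) {
    fit <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (fit$value < tol) break
    par <- fit$par + stats::rnorm(2, 0, 0.3)
  }
  if (fit$value >= 1e-6)
    stop_config(paste("beta calibration infeasible for centre %.2f,",
                      "coverage %.2f (residual %.2e)"), centre, coverage,
                sqrt(fit$value))
  list(alpha = exp(fit$par[1]), beta = exp(fit$par[2]),
       residual = sqrt(fit$value))
}

#' Reference pyramid: beta draws for accurate self-perception
#'
#' For each of the five self-perception bands (centres 0.1, 0.3, 0.5, 0.7,
#' 0.9) solves for beta-distribution parameters whose median sits at the
#' band centre and whose central 0.2-wide interval holds `coverage` of the
#' mass (0.75 by default), then draws `n` values per band. This is the
#' theoretical distribution of genetic ancestry were self-perception
#' accurate up to band resolution.
#'
#' @param n values drawn per band (fixed at the study sample size in the
#'   original use)
#' @param coverage central-interval mass in (0, 1)
#' @param seed integer seed
#' @return list: `samples` (n x 5 matrix, one column per band),
#'   `calibration` (data.frame: band, centre, alpha, beta, residual,
#'   empirical_mass)
#' @export
reference_pyramid <- function(n, coverage = 0.75, seed = NULL) {
  if (coverage <= 0 || coverage >= 1) stop_config("coverage must be in (0,1)")
  if (n < 1) stop_config("n must be >= 1")
  centres <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  with_seed(seed, {
    cal <- lapply(centres, .calibrate_beta, coverage = coverage)
    samples <- vapply(cal, function(cc) stats::rbeta(n, cc$alpha, cc$beta),
                      numeric(n))
    colnames(samples) <- paste0("band", 1:5)
    emp <- vapply(1:5, function(b) {
      lo <- max(centres[b] - 0.1, 0); hi <- min(centres[b] + 0.1, 1)
      mean(samples[, b] >= lo & samples[, b] <= hi)
    }, numeric(1))
    list(samples = samples,
         calibration = data.frame(
           band = 1:5, centre = centres,
           alpha = vapply(cal, `[[`, 0, "alpha"),
           beta = vapply(cal, `[[`, 0, "beta"),
           residual = vapply(cal, `[[`, 0, "residual"),
           empirical_mass = emp))
  })
}
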