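# regression: phenotype-on-ancestry models with covariates, delta-R2
# variance partitioning, method-of-moments errors-in-variables correction
# using the bootstrap SEs of the ancestry estimates, and Bonferroni trait
# scans. Native American ancestry is the baseline: European and African
# proportions enter as predictors (the three sum to 1).

#' Assemble an ancestry regression design
#'
#' Merges ancestry estimates (and their SEs) with the phenotype/metadata
#' table. European and African ancestry enter as `qEUR` and `qAFR`
#' (Native American baseline).
#'
#' @param estimates `ancestry_estimates` or N x K matrix with columns
#'   including EUR and AFR
#' @param pheno_geo per-individual data.frame (same row order)
#' @param se optional N x K matrix of ancestry SEs (e.g. [bootstrap_se()])
#' @param covariates character vector of covariate column names; `country`
#'   is treated as a factor with the alphabetically first level (Brazil in
#'   the default strata) as reference
#' @return object of class `ancestry_design`: list with `data`,
#'   `covariates`, `se` (columns qEUR, qAFR or NULL)
#' @export
ancestry_design <- function(estimates, pheno_geo, se = NULL,
                            covariates = c("age", "sex", "country",
                                           "education", "wealth_decile")) {
  q <- if (inherits(estimates, "ancestry_estimates")) estimates$q else as.matrix(estimates)
  if (!all(c("EUR", "AFR") %in% colnames(q)))
    stop_config("estimates need EUR and AFR components")
  if (nrow(q) != nrow(pheno_geo))
    stop_config("estimates and pheno_geo row counts differ")
  if (any(q[, "EUR"] + q[, "AFR"] > 1 + 1e-8, na.rm = TRUE))
    stop_config("qEUR + qAFR exceeds 1")
  covariates <- intersect(covariates, names(pheno_geo))
  dat <- data.frame(qEUR = q[, "EUR"], qAFR = q[, "AFR"],
                    pheno_geo, check.names = FALSE)
  if ("country" %in% names(dat)) dat$country <- factor(dat$country)
  se_mat <- NULL
  if (!is.null(se)) {
    se_mat <- cbind(qEUR = se[, "EUR"], qAFR = se[, "AFR"])
  }
  structure(list(data = dat, covariates = covariates, se = se_mat),
            class = "ancestry_design")
}

.design_formula <- function(trait, design, with_ancestry = TRUE,
                            extra_covariates = NULL) {
  rhs <- c(if (with_ancestry) c("qEUR", "qAFR"),
           design$covariates, extra_covariates)
  if (!length(rhs)) rhs <- "1"
  stats::reformulate(rhs, response = trait)
}

.check_rank <- function(fit) {
  a <- stats::alias(fit)$Complete
  if (!is.null(a) && nrow(a) > 0)
    stop_config("rank-deficient design; aliased columns: %s",
                paste(rownames(a), collapse = ", "))
  invisible(NULL)
}

#' Fit a phenotype-on-ancestry regression
#'
#' Multiple linear regression for continuous and ordinal traits (ordinal
#' traits entered as integer levels; an ordered-probit cross-check is
#' available via `probit_check`) or logistic regression for binary traits.
#' Complete cases only; exclusions are logged.
#'
#' @param design an [ancestry_design()]
#' @param trait column name of the response in `design$data`
#' @param family `"linear"` or `"logistic"`
#' @param extra_covariates additional columns (e.g. `c("BMI", "height")`
#'   for facial traits)
#' @param probit_check for linear fits of ordinal traits: also fit
#'   `MASS::polr` with a probit link and attach it as `probit`
#' @return object of class `regression_fit`: `coefficients` table
#'   (estimate, se, statistic, p), `r2` (McFadden pseudo-R2 for logistic,
#'   labelled by `r2_type`), `family`, `n_used`, the underlying `model`
#' @export
fit_phenotype_model <- function(design, trait,
                                family = c("linear", "logistic"),
                                extra_covariates = NULL,
                                probit_check = FALSE) {
  family <- match.arg(family)
  fml <- .design_formula(trait, design, TRUE, extra_covariates)
  vars <- all.vars(fml)
  dat <- design$data[stats::complete.cases(design$data[, vars]), vars]
  admix_log("%s: %d complete cases of %d", trait, nrow(dat), nrow(design$data))
  if (family == "logistic") {
    yv <- dat[[trait]]
    if (!all(yv %in% c(0, 1)))
      stop_config("logistic family needs a 0/1 trait; %s is not", trait)
    fit <- stats::glm(fml, data = dat, family = stats::binomial())
    r2 <- 1 - fit$deviance / fit$null.deviance
    r2_type <- "McFadden"
    cf <- summary(fit)$coefficients
  } else {
    fit <- stats::lm(fml, data = dat)
    .check_rank(fit)
    r2 <- summary(fit)$r.squared
    r2_type <- "OLS"
    cf <- summary(fit)$coefficients
  }
  out <- structure(list(
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              se = cf[, 2], statistic = cf[, 3], p = cf[, 4],
                              row.names = NULL),
    r2 = r2, r2_type = r2_type, family = family, n_used = nrow(dat),
    trait = trait, model = fit), class = "regression_fit")
  if (probit_check && family == "linear") {
    dat$.ord <- factor(dat[[trait]], ordered = TRUE)
    rhs <- attr(stats::terms(fml), "term.labels")
    out$probit <- MASS::polr(stats::reformulate(rhs, response = ".ord"),
                             data = dat, method = "probit", Hess = TRUE)
  }
  out
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit (%s) for %s: n = %d, R2(%s) = %.3f\n",
              x$family, x$trait, x$n_used, x$r2_type, x$r2))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Variance in a phenotype attributable to ancestry
#'
#' Fits the full model (covariates + ancestry) and the nested reduced model
#' (covariates only) on the identical complete-case rows and returns their
#' R2 difference: the proportion of trait variance explained by ancestry
#' over and above the covariates. Non-negative by nesting.
#'
#' @param design an [ancestry_design()]
#' @param trait response column name
#' @param extra_covariates as in [fit_phenotype_model()]
#' @return list: `r2_full`, `r2_reduced`, `delta_r2`
#' @export
delta_r2 <- function(design, trait, extra_covariates = NULL) {
  fml_full <- .design_formula(trait, design, TRUE, extra_covariates)
  fml_red <- .design_formula(trait, design, FALSE, extra_covariates)
  vars <- all.vars(fml_full)
  dat <- design$data[stats::complete.cases(design$data[, vars]), vars]
  f1 <- stats::lm(fml_full, data = dat)
  f0 <- stats::lm(fml_red, data = dat)
  if (stats::nobs(f1) != stats::nobs(f0))
    stop_config("full and reduced fits used different rows")
  r2f <- summary(f1)$r.squared; r2r <- summary(f0)$r.squared
  list(r2_full = r2f, r2_reduced = r2r, delta_r2 = max(0, r2f - r2r))
}

#' Errors-in-variables correction for ancestry predictors
#'
#' Ancestry proportions enter the regression as estimates with known
#' per-individual standard errors. Naive OLS attenuates their coefficients
#' toward zero. The method-of-moments correction subtracts the mean
#' measurement-error variance (diagonal, from se^2 averaged over
#' individuals) from the ancestry block of the predictor covariance before
#' solving the normal equations:
#'   beta = (S_xx - Lambda)^{-1} S_xy.
#' SEs for the corrected coefficients come from a sandwich estimator with
#' corrected residuals. In the scalar case this reproduces the classical
#' attenuation factor lambda = var(x*) / (var(x*) + var(e)).
#'
#' @param design an [ancestry_design()] carrying `se`
#' @param trait response column name
#' @param extra_covariates as in [fit_phenotype_model()]
#' @param shrinkage in \[0, 1\]: shrink the error-variance subtraction
#'   toward the naive fit (0 = full correction); use if the corrected
#'   covariance is not positive-definite
#' @return object of class `eiv_fit`: `naive` and `corrected` coefficient
#'   tables, `lambda` (mean error variances used), `n_used`
#' @export
eiv_adjust <- function(design, trait, extra_covariates = NULL,
                       shrinkage = 0) {
  if (is.null(design$se))
    stop_config("design carries no ancestry SEs; supply se= to ancestry_design()")
  fml <- .design_formula(trait, design, TRUE, extra_covariates)
  vars <- all.vars(fml)
  cc <- stats::complete.cases(design$data[, vars])
  dat <- design$data[cc, vars]
  se <- design$se[cc, , drop = FALSE]
  X <- stats::model.matrix(fml, data = dat)[, -1, drop = FALSE]
  y <- dat[[trait]]
  n <- nrow(X)
  xb <- colMeans(X); yb <- mean(y)
  Xc <- sweep(X, 2, xb); yc <- y - yb
  Sxx <- crossprod(Xc) / n
  Sxy <- crossprod(Xc, yc) / n
  beta_naive <- solve(Sxx, Sxy)
  Lambda <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  for (ac in c("qEUR", "qAFR"))
    Lambda[ac, ac] <- mean(se[, ac]^2)
  Sxx_star <- Sxx - (1 - shrinkage) * Lambda
  ev <- eigen(Sxx_star, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop_config(paste("corrected predictor covariance is not positive-definite;",
                      "increase the sample or set shrinkage > 0"))
  beta_corr <- solve(Sxx_star, Sxy)
  # sandwich SEs with corrected residuals (error-free part of X assumed)
  resid_corr <- yc - Xc %*% beta_corr
  meat <- crossprod(Xc * drop(resid_corr)) / n
  bread <- solve(Sxx_star)
  Vc <- bread %*% meat %*% bread / n
  resid_naive <- yc - Xc %*% beta_naive
  meat_n <- crossprod(Xc * drop(resid_naive)) / n
  bread_n <- solve(Sxx)
  Vn <- bread_n %*% meat_n %*% bread_n / n
  tab <- function(b, V) {
    se_ <- sqrt(diag(V))
    z <- drop(b) / se_
    data.frame(term = colnames(X), estimate = drop(b), se = se_,
               statistic = z, p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  }
  structure(list(naive = tab(beta_naive, Vn), corrected = tab(beta_corr, Vc),
                 lambda = diag(Lambda)[c("qEUR", "qAFR")],
                 intercept_naive = yb - sum(xb * beta_naive),
                 intercept_corrected = yb - sum(xb * beta_corr),
                 n_used = n, trait = trait, shrinkage = shrinkage),
            class = "eiv_fit")
}

#' @export
print.eiv_fit <- function(x, ...) {
  cat(sprintf("eiv_fit for %s (n = %d)\n  naive:\n", x$trait, x$n_used))
  print(x$naive[x$naive$term %in% c("qEUR", "qAFR"), ], digits = 3)
  cat("  corrected:\n")
  print(x$corrected[x$corrected$term %in% c("qEUR", "qAFR"), ], digits = 3)
  invisible(x)
}

#' Scan a list of traits with a Bonferroni family correction
#'
#' Fits each trait with [fit_phenotype_model()] and [delta_r2()] and flags
#' ancestry effects significant at the Bonferroni-adjusted per-test
#' threshold `alpha_family / length(traits)` (for a single trait the
#' threshold is the family alpha itself).
#'
#' @param design an [ancestry_design()]
#' @param traits character vector of trait columns; names may carry the
#'   family (`"linear"`/`"logistic"`), default linear
#' @param alpha_family family-wise error target (e.g. 0.018 over 18 traits
#'   gives the conventional 1e-3 per-test threshold)
#' @param extra_covariates as in [fit_phenotype_model()]
#' @return data.frame: trait, per-ancestry coefficient and p, r2,
#'   delta_r2, threshold, significant flags
#' @export
trait_scan <- function(design, traits, alpha_family = 0.05,
                       extra_covariates = NULL) {
  if (!length(traits)) stop_config("no traits to scan")
  fams <- if (is.null(names(traits))) rep("linear", length(traits)) else
    ifelse(names(traits) == "", "linear", names(traits))
  thr <- alpha_family / length(traits)
  rows <- lapply(seq_along(traits), function(i) {
    tr <- traits[[i]]
    fit <- fit_phenotype_model(design, tr, family = fams[i],
                               extra_covariates = extra_covariates)
    cf <- fit$coefficients
    ge <- cf[cf$term == "qEUR", ]; ga <- cf[cf$term == "qAFR", ]
    dr2 <- if (fams[i] == "linear")
      delta_r2(design, tr, extra_covariates)$delta_r2 else NA_real_
    data.frame(trait = tr, family = fams[i],
               coef_EUR = ge$estimate, p_EUR = ge$p,
               coef_AFR = ga$estimate, p_AFR = ga$p,
               r2 = fit$r2, delta_r2 = dr2, n_used = fit$n_used,
               threshold = thr,
               sig_EUR = ge$p < thr, sig_AFR = ga$p < thr)
  })
  do.call(rbind, rows)
}
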