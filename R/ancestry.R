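# ancestry: supervised maximum-likelihood estimation of individual K-way
# admixture proportions with parental allele frequencies held fixed, plus
# marker-bootstrap standard errors.
#
# Model: genotype g_ij ~ Binomial(2, p_ij), p_ij = sum_k q_ik f_jk.
# log L_i(q) = sum_j [ g_ij log p_ij + (2 - g_ij) log(1 - p_ij) ]
# maximized over the K-simplex by the multiplicative EM update
#   q_k <- q_k * (1 / 2M') * sum_j [ g_j f_jk / p_j + (2-g_j)(1-f_jk)/(1-p_j) ]
# with M' the count of non-missing markers. The per-individual problem is
# concave in q for fixed f, so uniform initialization affects only the
# iteration count.

.FREQ_CLAMP <- 1e-6

# vectorized across individuals; G: N x M with NA missing, FF: M x K
.em_ancestry <- function(G, FF, tol = 1e-7, max_iter = 2000L,
                         assert_monotone = FALSE) {
  N <- nrow(G); M <- nrow(FF); K <- ncol(FF)
  FF <- pmin(pmax(FF, .FREQ_CLAMP), 1 - .FREQ_CLAMP)
  W <- !is.na(G)
  G0 <- G; G0[!W] <- 0L
  G0 <- matrix(as.numeric(G0), N, M)
  G2 <- (2 - G0) * W                       # (2 - g) masked to non-missing
  G0 <- G0 * W
  Mprime <- rowSums(W)
  ok <- Mprime > 0
  Q <- matrix(1 / K, N, K)
  FC <- 1 - FF
  loglik_of <- function(Q) {
    P <- Q %*% t(FF)
    rowSums(G0 * log(P) + G2 * log(1 - P))
  }
  ll <- loglik_of(Q)
  n_iter <- rep(0L, N); converged <- rep(FALSE, N)
  active <- which(ok)
  tFF <- t(FF); tFC <- t(FC)
  for (it in seq_len(max_iter)) {
    if (!length(active)) break
    Qa <- Q[active, , drop = FALSE]
    G0a <- G0[active, , drop = FALSE]
    G2a <- G2[active, , drop = FALSE]
    P <- Qa %*% tFF
    A <- (G0a / P) %*% FF + (G2a / (1 - P)) %*% FC
    Qn <- Qa * A / (2 * Mprime[active])
    Qn <- Qn / rowSums(Qn)                 # guard accumulation error
    Q[active, ] <- Qn
    Pn <- Qn %*% tFF
    lln <- rowSums(G0a * log(Pn) + G2a * log(1 - Pn))
    gain <- lln - ll[active]
    if (assert_monotone && any(gain < -1e-8 * pmax(1, abs(lln))))
      stop("EM log-likelihood decreased; this indicates a numerical defect")
    ll[active] <- lln
    n_iter[active] <- it
    done <- gain < tol
    converged[active[done]] <- TRUE
    active <- active[!done]
  }
  Q[!ok, ] <- NA_real_
  list(q = Q, loglik = ll, n_iter = n_iter,
       converged = converged | !ok, estimable = ok)
}

#' Estimate individual ancestry proportions (supervised)
#'
#' Maximizes the binomial admixture likelihood per individual over the
#' K-simplex with parental allele frequencies fixed at the panel values,
#' using multiplicative EM updates. Panel frequencies are clamped to
#' \[1e-6, 1 - 1e-6\] before evaluation so that markers monomorphic in one
#' parental population (a designed feature of ancestry-informative panels)
#' do not produce log(0). Missing genotypes contribute nothing; an
#' individual with zero non-missing markers gets a flagged all-`NA`
#' estimate. When every population shares identical frequencies the
#' likelihood is flat in q: the estimate stays at the uniform
#' initialization and `identifiable` is set to FALSE.
#'
#' @param genotypes a [genotype_matrix()] aligned with `panel`
#' @param panel a [parental_panel()]
#' @param tol convergence threshold on the log-likelihood gain
#' @param max_iter maximum EM iterations
#' @return object of class `ancestry_estimates`: list with `q` (N x K),
#'   `loglik`, `n_iter`, `converged`, `identifiable`, `populations`
#' @export
estimate_ancestry <- function(genotypes, panel, tol = 1e-7, max_iter = 5000L) {
  if (!all(colnames(genotypes) == panel$marker_ids))
    stop_config("genotypes and panel are not aligned; run align_panel() first")
  if (ncol(panel$freqs) < 2) stop_config("panel needs K >= 2 populations")
  FF <- panel$freqs
  flat <- all(abs(FF - FF[, 1]) < 1e-12)
  fit <- .em_ancestry(unclass(genotypes), FF, tol = tol, max_iter = max_iter,
                      assert_monotone = TRUE)
  dimnames(fit$q) <- list(rownames(genotypes), panel$population_labels)
  structure(list(q = fit$q, loglik = fit$loglik, n_iter = fit$n_iter,
                 converged = fit$converged,
                 identifiable = !flat,
                 populations = panel$population_labels),
            class = "ancestry_estimates")
}

#' @export
print.ancestry_estimates <- function(x, ...) {
  cat(sprintf("ancestry_estimates: %d individuals, K = %d (%s)\n",
              nrow(x$q), ncol(x$q), paste(x$populations, collapse = "/")))
  cat(sprintf("  mean q: %s\n",
              paste(sprintf("%s=%.3f", x$populations, colMeans(x$q, na.rm = TRUE)),
                    collapse = " ")))
  if (!x$identifiable)
    cat("  WARNING: parental frequencies identical across populations; q not identifiable\n")
  invisible(x)
}

#' Bootstrap standard errors for ancestry estimates
#'
#' Resamples markers with replacement B times (parental frequencies treated
#' as fixed), re-estimates q for every individual, and returns the
#' per-component standard deviation across replicates.
#'
#' @param genotypes a [genotype_matrix()] aligned with `panel`
#' @param panel a [parental_panel()]
#' @param B number of bootstrap replicates (default 200)
#' @param seed integer seed
#' @param tol,max_iter passed to the EM
#' @return N x K matrix of standard errors
#' @export
bootstrap_se <- function(genotypes, panel, B = 200L, seed = NULL,
                         tol = 1e-5, max_iter = 1000L) {
  if (B < 2) stop_config("B must be >= 2")
  G <- unclass(genotypes); FF <- panel$freqs
  M <- ncol(G); N <- nrow(G); K <- ncol(FF)
  with_seed(seed, {
    acc <- matrix(0, N, K); acc2 <- matrix(0, N, K)
    for (b in seq_len(B)) {
      jj <- sample.int(M, M, replace = TRUE)
      qb <- .em_ancestry(G[, jj, drop = FALSE], FF[jj, , drop = FALSE],
                         tol = tol, max_iter = max_iter)$q
      acc <- acc + qb; acc2 <- acc2 + qb^2
    }
    se <- sqrt(pmax((acc2 - acc^2 / B) / (B - 1), 0))
    dimnames(se) <- list(rownames(G), panel$population_labels)
    se
  })
}

#' Estimate parental allele frequencies from reference genotypes
#'
#' Completeness helper: allele counting within labelled reference samples.
#'
#' @param genotypes a [genotype_matrix()] of reference individuals
#' @param population factor/character of population labels per individual
#' @return a [parental_panel()]
#' @export
panel_from_reference <- function(genotypes, population) {
  population <- as.factor(population)
  f <- vapply(levels(population), function(p) {
    colMeans(genotypes[population == p, , drop = FALSE], na.rm = TRUE) / 2
  }, numeric(ncol(genotypes)))
  parental_panel(f, marker_ids = colnames(genotypes),
                 population_labels = levels(population))
}

#' Exhaustive simplex grid-search reference maximizer
#'
#' Independent check of the EM: evaluates the admixture log-likelihood on a
#' regular simplex grid with the given step and returns the best grid point
#' per individual. Intended for validation at small step counts, not as an
#' estimator.
#'
#' @param genotypes,panel as in [estimate_ancestry()]
#' @param step grid resolution on the simplex (default 0.01)
#' @return N x K matrix of best grid points
#' @export
grid_search_ancestry <- function(genotypes, panel, step = 0.01) {
  FF <- pmin(pmax(panel$freqs, .FREQ_CLAMP), 1 - .FREQ_CLAMP)
  K <- ncol(FF)
  stopifnot(K == 3)   # grid enumeration implemented for the 3-way case
  s <- round(1 / step)
  pts <- list()
  for (a in 0:s) for (b in 0:(s - a))
    pts[[length(pts) + 1L]] <- c(a, b, s - a - b) / s
  Qg <- do.call(rbind, pts)
  G <- unclass(genotypes)
  W <- !is.na(G); G0 <- G; G0[!W] <- 0L
  G0 <- matrix(as.numeric(G0), nrow(G)) * W
  G2 <- (2 - G0) * W
  P <- Qg %*% t(FF)
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  LL <- G0 %*% t(log(P)) + G2 %*% t(log(1 - P))   # N x n_grid
  best <- max.col(LL, ties.method = "first")
  out <- Qg[best, , drop = FALSE]
  dimnames(out) <- list(rownames(G), panel$population_labels)
  out
}
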