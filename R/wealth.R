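# wealth: polychoric principal-component wealth index from ordinal
# household-asset items, with within-country decile conversion.

# standard bivariate normal CDF P(X <= a, Y <= b; rho) via the conditional
# identity  Phi2(a,b,rho) = int_{-inf}^a phi(x) Phi((b - rho x)/sqrt(1-rho^2)) dx
.pbvnorm <- function(a, b, rho) {
  if (!is.finite(a) && a > 0) return(stats::pnorm(b))
  if (!is.finite(b) && b > 0) return(stats::pnorm(a))
  if (!is.finite(a) || !is.finite(b)) {
    if (a == -Inf || b == -Inf) return(0)
  }
  if (abs(rho) < 1e-12) return(stats::pnorm(a) * stats::pnorm(b))
  sr <- sqrt(1 - rho^2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((b - rho * x) / sr)
  stats::integrate(f, -Inf, a, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Polychoric correlation (two-step estimator)
#'
#' Thresholds are fixed at normal quantiles of the marginal cumulative
#' category proportions; the latent correlation is then estimated by
#' maximizing the bivariate-normal cell-probability likelihood over
#' (-1, 1). Empty cells are handled by the likelihood itself (no
#' continuity correction).
#'
#' @param x,y ordinal vectors (integer codes), each with >= 2 observed
#'   levels; n >= 20 recommended
#' @return list: `rho`, `thresholds_x`, `thresholds_y`, `loglik`
#' @export
polychoric_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop_config("polychoric correlation needs >= 2 levels in both variables")
  tab <- table(factor(x), factor(y))
  tx <- stats::qnorm(cumsum(rowSums(tab)) / sum(tab))  # last = +Inf
  ty <- stats::qnorm(cumsum(colSums(tab)) / sum(tab))
  ax <- c(-Inf, tx[-length(tx)], Inf)
  ay <- c(-Inf, ty[-length(ty)], Inf)
  nr <- nrow(tab); nc <- ncol(tab)
  negll <- function(rho) {
    Phi <- outer(seq_len(nr + 1), seq_len(nc + 1),
                 Vectorize(function(i, j) .pbvnorm(ax[i], ay[j], rho)))
    P <- Phi[-1, -1] - Phi[-(nr + 1), -1] - Phi[-1, -(nc + 1)] +
      Phi[-(nr + 1), -(nc + 1)]
    P <- pmax(P, 1e-12)
    -sum(tab * log(P))
  }
  opt <- stats::optimize(negll, c(-0.999, 0.999), tol = 1e-7)
  list(rho = opt$minimum, thresholds_x = tx[-length(tx)],
       thresholds_y = ty[-length(ty)], loglik = -opt$objective)
}

#' Polychoric correlation matrix of an item table
#'
#' @param items data.frame of ordinal items (integer codes)
#' @return symmetric correlation matrix
#' @export
polychoric_matrix <- function(items) {
  p <- ncol(items)
  R <- diag(1, p)
  dimnames(R) <- list(names(items), names(items))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    R[i, j] <- R[j, i] <- polychoric_corr(items[[i]], items[[j]])$rho
  }
  R
}

#' Polychoric principal-component wealth index
#'
#' Per country: the polychoric correlation matrix of the asset items is
#' computed (repaired by eigenvalue clipping if not positive-semidefinite),
#' its first eigenvector taken as item weights, and each individual scored
#' as the weighted sum of standardized item codes. The index sign is
#' oriented so that it correlates positively with the `anchor` item.
#' Scores are converted to deciles 1-10 within each country (average-rank
#' tie handling); countries with fewer than 10 individuals have their
#' deciles flagged unreliable.
#'
#' @param assets data.frame with `sample_id`, `country` and ordinal item
#'   columns
#' @param anchor item whose positive direction defines "wealthier"
#'   (default `"bathrooms"` if present, else the first item)
#' @return data.frame: sample_id, country, score, decile,
#'   decile_reliable; per-country first-eigenvector variance shares
#'   attached as attribute `"variance_share"`
#' @export
wealth_index <- function(assets, anchor = NULL) {
  items <- setdiff(names(assets), c("sample_id", "country"))
  if (is.null(anchor))
    anchor <- if ("bathrooms" %in% items) "bathrooms" else items[1]
  rows_missing <- !stats::complete.cases(assets[, items])
  if (any(rows_missing))
    admix_log("excluding %d rows with missing asset items", sum(rows_missing))
  assets <- assets[!rows_missing, , drop = FALSE]
  out <- vector("list", 0)
  vshare <- c()
  for (cn in unique(assets$country)) {
    sub <- assets[assets$country == cn, , drop = FALSE]
    usable <- items[vapply(items, function(it)
      length(unique(sub[[it]])) >= 2, logical(1))]
    R <- polychoric_matrix(sub[, usable])
    eg <- eigen(R, symmetric = TRUE)
    if (min(eg$values) < 0) {
      warning(sprintf("polychoric matrix for %s not PSD; clipping eigenvalues", cn))
      vals <- pmax(eg$values, 1e-8)
      R <- eg$vectors %*% diag(vals) %*% t(eg$vectors)
      eg <- eigen(R, symmetric = TRUE)
    }
    w <- eg$vectors[, 1]
    Z <- scale(as.matrix(sub[, usable]))
    score <- drop(Z %*% w)
    if (stats::cor(score, sub[[anchor]]) < 0) score <- -score
    rel <- nrow(sub) >= 10
    if (!rel) admix_log("country %s has < 10 individuals; deciles unreliable", cn)
    dec <- as.integer(ceiling(10 * rank(score, ties.method = "average") /
                                (nrow(sub) + 1)))
    dec <- pmin(pmax(dec, 1L), 10L)
    out[[cn]] <- data.frame(sample_id = sub$sample_id, country = cn,
                            score = score, decile = dec,
                            decile_reliable = rel,
                            stringsAsFactors = FALSE)
    vshare[cn] <- eg$values[1] / sum(eg$values)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "variance_share") <- vshare
  res
}
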