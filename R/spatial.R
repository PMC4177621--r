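# spatial: location aggregation, Moran's I and canonical-correlation
# permutation tests against the null of spatially uniform ancestry,
# ordinary-kriging interpolation surfaces, and census-size correlations.
# Distances are great-circle (haversine, km) on WGS84 lat/lon: at country
# scale a planar approximation is materially wrong for e.g. Brazil.

.haversine_km <- function(coords) {
  # coords: matrix/data.frame with columns lon, lat (degrees); extra
  # columns (ids, summaries) are ignored when named columns are present
  geosphere::distm(.lonlat(coords), fun = geosphere::distHaversine) / 1000
}

.lonlat <- function(coords) {
  if (is.data.frame(coords) && all(c("lon", "lat") %in% names(coords)))
    return(cbind(coords$lon, coords$lat))
  as.matrix(coords)[, 1:2, drop = FALSE]
}

#' Aggregate individual ancestry by birthplace
#'
#' @param estimates an `ancestry_estimates` object (or a bare N x K matrix
#'   of proportions)
#' @param pheno_geo data.frame with `birthplace_id`, `birth_lat`,
#'   `birth_lon` and optionally `census_size`, `altitude`, rows matching
#'   `estimates`
#' @return data.frame, one row per unique birthplace: coordinates, n,
#'   per-component mean (`mean_<pop>`) and standard deviation
#'   (`sd_<pop>`, `NA` where n < 2), census size
#' @export
aggregate_by_location <- function(estimates, pheno_geo) {
  q <- if (inherits(estimates, "ancestry_estimates")) estimates$q else as.matrix(estimates)
  if (nrow(q) != nrow(pheno_geo))
    stop_config("estimates and pheno_geo row counts differ")
  if (any(is.na(pheno_geo$birth_lat) | is.na(pheno_geo$birth_lon)))
    stop_config("every individual needs coordinates")
  id <- pheno_geo$birthplace_id
  ids <- sort(unique(id))
  idx <- split(seq_len(nrow(q)), id)[ids]
  pops <- colnames(q)
  out <- data.frame(birthplace_id = ids,
                    lat = vapply(idx, function(i) pheno_geo$birth_lat[i[1]], 0),
                    lon = vapply(idx, function(i) pheno_geo$birth_lon[i[1]], 0),
                    n = lengths(idx))
  for (p in pops) {
    out[[paste0("mean_", p)]] <- vapply(idx, function(i) mean(q[i, p]), 0)
    out[[paste0("sd_", p)]] <- vapply(idx, function(i)
      if (length(i) >= 2) stats::sd(q[i, p]) else NA_real_, 0)
  }
  for (extra in c("census_size", "altitude"))
    if (extra %in% names(pheno_geo))
      out[[extra]] <- vapply(idx, function(i) pheno_geo[[extra]][i[1]], 0)
  out
}

#' Row-standardized spatial weights
#'
#' @param coords matrix/data.frame with columns `lon`, `lat` in degrees
#' @param scheme `"idw"` (inverse great-circle distance, default) or
#'   `"knn"` (k nearest neighbours, binary then row-standardized)
#' @param k neighbours for the knn scheme
#' @return n x n row-standardized weight matrix with zero diagonal
#' @export
spatial_weights <- function(coords, scheme = c("idw", "knn"), k = 5) {
  scheme <- match.arg(scheme)
  D <- .haversine_km(coords)
  n <- nrow(D)
  if (scheme == "idw") {
    W <- 1 / D
    diag(W) <- 0
    W[is.infinite(W)] <- max(W[is.finite(W)]) # coincident points: strongest tie
  } else {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[-1][seq_len(min(k, n - 1))]
      W[i, nb] <- 1
    }
  }
  W / rowSums(W)
}

#' Moran's I spatial autocorrelation
#'
#' I = (n / S0) * sum_ij w_ij (v_i - vbar)(v_j - vbar) / sum_i (v_i - vbar)^2
#' with S0 = sum w_ij. Under spatial randomness E\[I\] = -1/(n-1).
#'
#' @param values numeric vector, one per location
#' @param coords matrix/data.frame with `lon`, `lat` columns (ignored if
#'   `weights` given)
#' @param weights optional precomputed weight matrix (e.g.
#'   [spatial_weights()])
#' @param scheme,k passed to [spatial_weights()] when `weights` is NULL
#' @return scalar I
#' @export
morans_i <- function(values, coords = NULL, weights = NULL,
                     scheme = "idw", k = 5) {
  n <- length(values)
  if (n < 3) stop_config("Moran's I needs at least 3 locations")
  if (stats::var(values) == 0)
    stop_config("Moran's I undefined for constant values (zero variance)")
  if (is.null(weights)) weights <- spatial_weights(coords, scheme, k)
  z <- values - mean(values)
  s0 <- sum(weights)
  (n / s0) * drop(z %*% weights %*% z) / sum(z^2)
}

#' Permutation test for a spatial statistic of location means
#'
#' Permutes the assignment of individuals to birthplaces, keeping the
#' number of individuals per location fixed, recomputes the per-location
#' means and the statistic after each permutation, and returns
#' p = (1 + #\{|stat_perm| >= |stat_obs|\}) / (n_perm + 1).
#'
#' @param values per-individual numeric vector or matrix (columns averaged
#'   per location)
#' @param location_id per-individual birthplace identifier
#' @param coords data.frame of unique locations with `birthplace_id`,
#'   `lon`, `lat` (order defines the location order fed to `statistic_fn`)
#' @param statistic_fn function(location_means, coords) -> scalar; e.g. a
#'   closure around [morans_i()] or [canonical_correlation_geo()]
#' @param n_perm number of permutations (>= 99; default 999)
#' @param seed integer seed
#' @return list: `statistic` (observed), `p`, `perm` (permuted values)
#' @export
permutation_test_spatial <- function(values, location_id, coords,
                                     statistic_fn, n_perm = 999L,
                                     seed = NULL) {
  if (n_perm < 99) stop_config("use at least 99 permutations")
  values <- as.matrix(values)
  fac <- factor(location_id, levels = coords$birthplace_id)
  if (anyNA(fac)) stop_config("location_id contains ids absent from coords")
  counts <- as.integer(table(fac))
  keep <- counts > 0
  # rowsum returns one row per present group, in factor level order
  loc_means <- function(f) rowsum(values, f) / counts[keep]
  obs <- statistic_fn(loc_means(fac), coords[keep, , drop = FALSE])
  with_seed(seed, {
    perm_stats <- vapply(seq_len(n_perm), function(b) {
      fp <- sample(fac)
      tryCatch(statistic_fn(loc_means(fp), coords[keep, , drop = FALSE]),
               error = function(e) stop_config(
                 "statistic failed on permutation %d: %s", b, conditionMessage(e)))
    }, numeric(1))
    p <- (1 + sum(abs(perm_stats) >= abs(obs))) / (n_perm + 1)
    list(statistic = obs, p = p, perm = perm_stats)
  })
}

# polynomial expansion of (lat, lon) up to total degree d, aliased columns
# dropped by pivoted QR if the expansion is collinear
.geo_poly <- function(coords, degree) {
  lat <- scale(coords$lat)[, 1]; lon <- scale(coords$lon)[, 1]
  cols <- list()
  for (i in 0:degree) for (j in 0:degree) {
    if (i + j == 0 || i + j > degree) next
    cols[[sprintf("lat%d.lon%d", i, j)]] <- lat^i * lon^j
  }
  X <- do.call(cbind, cols)
  qr_ <- qr(cbind(1, X))
  if (qr_$rank < ncol(X) + 1) {
    keep <- setdiff(qr_$pivot[seq_len(qr_$rank)], 1L) - 1L
    warning("collinear geographic polynomial expansion; dropping aliased terms")
    X <- X[, keep, drop = FALSE]
  }
  X
}

#' Canonical correlation of ancestry with geographic coordinates
#'
#' Canonical correlations between the K-1 free ancestry columns (the last
#' component is omitted since rows sum to 1) and a polynomial expansion of
#' (lat, lon) up to the given total degree. Quadratic and cubic terms
#' accommodate curved ancestry gradients. Significance, when requested, by
#' the same birthplace-permutation scheme as Moran's I, applied to the
#' first canonical correlation.
#'
#' @param q_matrix N x K (or n_loc x K) ancestry proportions
#' @param coords matching data.frame with `lat`, `lon`
#' @param degree polynomial degree in 1:4
#' @param location_id,n_perm,seed if `location_id` is supplied the inputs
#'   are per-individual: means per location are tested with `n_perm`
#'   permutations
#' @return list: `cancor` (vector of canonical correlations), and when
#'   permuting also `p`
#' @export
canonical_correlation_geo <- function(q_matrix, coords, degree = 3,
                                      location_id = NULL, n_perm = 999L,
                                      seed = NULL) {
  if (!degree %in% 1:4) stop_config("degree must be in 1..4")
  q_matrix <- as.matrix(q_matrix)
  cc_of <- function(qm, xy) {
    Y <- qm[, -ncol(qm), drop = FALSE]
    X <- .geo_poly(xy, degree)
    if (nrow(X) <= ncol(X) + ncol(Y))
      stop_config("too few locations (%d) for a degree-%d expansion", nrow(X), degree)
    stats::cancor(X, Y)$cor
  }
  if (is.null(location_id)) {
    list(cancor = cc_of(q_matrix, coords))
  } else {
    uloc <- unique(data.frame(birthplace_id = location_id,
                              lat = coords$lat, lon = coords$lon))
    res <- permutation_test_spatial(q_matrix, location_id, uloc,
                                    function(m, xy) cc_of(m, xy)[1],
                                    n_perm = n_perm, seed = seed)
    full <- cc_of(rowsum(q_matrix, factor(location_id, uloc$birthplace_id)) /
                    as.integer(table(factor(location_id, uloc$birthplace_id))),
                  uloc)
    list(cancor = full, p = res$p, first_cc = res$statistic)
  }
}

# --- variogram + ordinary kriging ------------------------------------------

.vgm_model <- function(h, nugget, psill, range_, model) {
  if (model == "spherical") {
    g <- ifelse(h >= range_, nugget + psill,
                nugget + psill * (1.5 * h / range_ - 0.5 * (h / range_)^3))
  } else {  # exponential with practical range
    g <- nugget + psill * (1 - exp(-3 * h / range_))
  }
  ifelse(h == 0, 0, g)
}

# empirical semivariogram (equal-width bins to half the max distance) and
# WLS fit with Cressie weights N_h / gamma^2
.fit_variogram <- function(D, v, model, nugget, n_bins = 12) {
  iu <- which(upper.tri(D), arr.ind = TRUE)
  h <- D[iu]; sv <- 0.5 * (v[iu[, 1]] - v[iu[, 2]])^2
  cutoff <- max(h) / 2
  ok <- h <= cutoff & h > 0
  if (!any(ok)) return(NULL)
  bins <- cut(h[ok], seq(0, cutoff, length.out = n_bins + 1))
  hb <- tapply(h[ok], bins, mean)
  gb <- tapply(sv[ok], bins, mean)
  nb <- tapply(sv[ok], bins, length)
  use <- !is.na(gb)
  if (sum(use) < 3 || all(gb[use] < 1e-12)) return(NULL)
  hb <- hb[use]; gb <- gb[use]; nb <- nb[use]
  obj <- function(par) {
    ps <- exp(par[1]); rg <- exp(par[2])
    ng <- if (is.null(nugget)) exp(par[3]) else nugget
    gm <- .vgm_model(hb, ng, ps, rg, model)
    sum(nb * (gb - gm)^2 / pmax(gm, 1e-10)^2)
  }
  init <- c(log(max(gb)), log(cutoff / 2), if (is.null(nugget)) log(max(gb) / 10))
  fit <- tryCatch(stats::optim(init, obj, method = "Nelder-Mead",
                               control = list(maxit = 2000)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  ps <- exp(fit$par[1]); rg <- exp(fit$par[2])
  ng <- if (is.null(nugget)) exp(fit$par[3]) else nugget
  if (!is.finite(ps) || !is.finite(rg) || ps < 1e-12) return(NULL)
  list(nugget = ng, psill = ps, range = rg, model = model,
       empirical = data.frame(h = hb, gamma = gb, n = nb))
}

#' Ordinary-kriging surface of location mean ancestry
#'
#' Fits an empirical semivariogram of the location means by weighted least
#' squares (spherical model by default) and solves the ordinary-kriging
#' system on a regular lat/lon grid over the data bounding box. With a
#' zero nugget the surface honours the observed means exactly at data
#' locations. Predictions are clipped to \[0, 1\]. If the variogram fit is
#' degenerate (e.g. a near-constant field) the function falls back to
#' inverse-distance weighting with a warning.
#'
#' @param summaries output of [aggregate_by_location()]
#' @param component ancestry component name (e.g. `"NAM"`)
#' @param grid_spec list with `nx`, `ny` (default 50 x 50)
#' @param variogram `"spherical"` or `"exponential"`
#' @param nugget fixed nugget (default 0); `NULL` to estimate
#' @return object of class `krige_grid`: data.frame `grid` (lat, lon,
#'   prediction, variance), the fitted `variogram`, and `method`
#' @export
krige_surface <- function(summaries, component,
                          grid_spec = list(nx = 50, ny = 50),
                          variogram = c("spherical", "exponential"),
                          nugget = 0) {
  variogram <- match.arg(variogram)
  vcol <- paste0("mean_", component)
  if (!vcol %in% names(summaries)) stop_config("no column %s in summaries", vcol)
  if (nrow(summaries) < 5) stop_config("kriging needs at least 5 locations")
  v <- summaries[[vcol]]
  pts <- cbind(lon = summaries$lon, lat = summaries$lat)
  D <- .haversine_km(pts)
  gx <- seq(min(summaries$lon), max(summaries$lon), length.out = grid_spec$nx)
  gy <- seq(min(summaries$lat), max(summaries$lat), length.out = grid_spec$ny)
  grid <- expand.grid(lon = gx, lat = gy)
  D0 <- geosphere::distm(pts, as.matrix(grid),
                         fun = geosphere::distHaversine) / 1000
  vg <- .fit_variogram(D, v, variogram, nugget)
  n <- nrow(pts)
  if (is.null(vg)) {
    warning("degenerate variogram fit; falling back to inverse-distance weighting")
    W <- 1 / pmax(D0, 1e-9)^2
    pred <- colSums(W * v) / colSums(W)
    at_data <- apply(D0, 2, function(d) { i <- which.min(d); if (d[i] < 1e-9) i else NA })
    pred[!is.na(at_data)] <- v[at_data[!is.na(at_data)]]
    out <- data.frame(grid, prediction = pmin(pmax(pred, 0), 1), variance = NA_real_)
    return(structure(list(grid = out, variogram = NULL, method = "idw",
                          component = component), class = "krige_grid"))
  }
  G <- .vgm_model(D, vg$nugget, vg$psill, vg$range, variogram)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  g0 <- .vgm_model(D0, vg$nugget, vg$psill, vg$range, variogram)
  B <- rbind(g0, 1)
  Wl <- tryCatch(solve(A, B), error = function(e) NULL)
  if (is.null(Wl)) {
    Wl <- MASS::ginv(A) %*% B
  }
  w <- Wl[seq_len(n), , drop = FALSE]
  mu <- Wl[n + 1, ]
  pred <- drop(crossprod(w, v))
  pvar <- pmax(0, colSums(w * g0) + mu)
  out <- data.frame(grid, prediction = pmin(pmax(pred, 0), 1), variance = pvar)
  structure(list(grid = out, variogram = vg, method = "ordinary_kriging",
                 component = component), class = "krige_grid")
}

#' Predict at arbitrary points from a fitted kriging setup
#'
#' Convenience wrapper: kriging prediction at the supplied points rather
#' than a regular grid (used e.g. to verify exactness at data locations).
#'
#' @param summaries,component,variogram,nugget as [krige_surface()]
#' @param newdata data.frame with `lat`, `lon`
#' @return numeric predictions, clipped to \[0, 1\]
#' @export
krige_predict <- function(summaries, component, newdata,
                          variogram = "spherical", nugget = 0) {
  vcol <- paste0("mean_", component)
  v <- summaries[[vcol]]
  pts <- cbind(lon = summaries$lon, lat = summaries$lat)
  D <- .haversine_km(pts)
  vg <- .fit_variogram(D, v, variogram, nugget)
  if (is.null(vg)) stop_config("degenerate variogram; no kriging prediction")
  n <- nrow(pts)
  G <- .vgm_model(D, vg$nugget, vg$psill, vg$range, variogram)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  D0 <- geosphere::distm(pts, cbind(newdata$lon, newdata$lat),
                         fun = geosphere::distHaversine) / 1000
  B <- rbind(.vgm_model(D0, vg$nugget, vg$psill, vg$range, variogram), 1)
  Wl <- solve(A, B)
  pmin(pmax(drop(crossprod(Wl[seq_len(n), , drop = FALSE], v)), 0), 1)
}

#' Census-size correlations
#'
#' Spearman rank correlations (settlement sizes are heavy-tailed, so rank
#' based) of (i) per-location volunteer count vs census size and (ii)
#' per-location ancestry standard deviation vs census size, the latter
#' restricted to locations with at least `min_n` individuals. Permutation
#' p-values permute census sizes across birthplaces.
#'
#' @param summaries output of [aggregate_by_location()] including
#'   `census_size`
#' @param min_n minimum individuals per location for the sd analysis
#'   (default 10)
#' @param min_locations minimum qualifying locations (default 10); below
#'   this the sd analysis is skipped with a log message
#' @param n_perm,seed permutation settings
#' @return data.frame: analysis, component, rho, p, n_locations
#' @export
census_correlations <- function(summaries, min_n = 10, min_locations = 10,
                                n_perm = 999L, seed = NULL) {
  if (!"census_size" %in% names(summaries))
    stop_config("summaries lack census_size")
  if (stats::var(summaries$census_size) == 0) {
    admix_log("census size constant; correlations undefined", level = "warn")
    return(data.frame(analysis = "count_vs_census", component = NA,
                      rho = NA_real_, p = NA_real_,
                      n_locations = nrow(summaries), flagged = TRUE))
  }
  perm_p <- function(x, y) {
    obs <- stats::cor(x, y, method = "spearman")
    with_seed(seed, {
      ps <- vapply(seq_len(n_perm), function(b)
        stats::cor(x, sample(y), method = "spearman"), numeric(1))
      (1 + sum(abs(ps) >= abs(obs))) / (n_perm + 1)
    })
  }
  rows <- list(data.frame(
    analysis = "count_vs_census", component = NA_character_,
    rho = stats::cor(summaries$n, summaries$census_size, method = "spearman"),
    p = perm_p(summaries$n, summaries$census_size),
    n_locations = nrow(summaries), flagged = FALSE))
  big <- summaries[summaries$n >= min_n, , drop = FALSE]
  sdcols <- grep("^sd_", names(summaries), value = TRUE)
  if (nrow(big) < min_locations) {
    admix_log("only %d locations with n >= %d; sd-vs-census analysis skipped",
              nrow(big), min_n, level = "warn")
  } else {
    for (sc in sdcols) {
      rows[[length(rows) + 1]] <- data.frame(
        analysis = "sd_vs_census", component = sub("^sd_", "", sc),
        rho = stats::cor(big[[sc]], big$census_size, method = "spearman"),
        p = perm_p(big[[sc]], big$census_size),
        n_locations = nrow(big), flagged = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Correlation of ancestry with altitude of birthplace
#'
#' @param estimates `ancestry_estimates` or N x K matrix
#' @param pheno_geo data.frame with `altitude`
#' @return data.frame: component, r, p (Pearson, two-sided), flagged
#' @export
altitude_correlation <- function(estimates, pheno_geo) {
  q <- if (inherits(estimates, "ancestry_estimates")) estimates$q else as.matrix(estimates)
  if (!"altitude" %in% names(pheno_geo)) stop_config("pheno_geo lacks altitude")
  alt <- pheno_geo$altitude
  if (stats::var(alt, na.rm = TRUE) == 0)
    return(data.frame(component = colnames(q), r = NA_real_, p = NA_real_,
                      flagged = TRUE))
  do.call(rbind, lapply(colnames(q), function(k) {
    if (stats::var(q[, k], na.rm = TRUE) == 0)
      return(data.frame(component = k, r = NA_real_, p = NA_real_,
                        flagged = TRUE))
    ct <- stats::cor.test(q[, k], alt)
    data.frame(component = k, r = unname(ct$estimate), p = ct$p.value,
               flagged = FALSE)
  }))
}

#' Type-I-error calibration of the spatial permutation tests
#'
#' Monte-Carlo diagnostic: generates replicate cohorts with no spatial
#' structure (individuals assigned to fixed locations uniformly at random;
#' ancestry iid Dirichlet, identical everywhere), runs the Moran's-I and
#' first-canonical-correlation permutation tests on each, and reports the
#' rejection rate at the requested alpha levels. Under the null the tests
#' are exact, so rates should sit inside the binomial interval around
#' alpha.
#'
#' @param n_reps null replicates (default 500)
#' @param n_perm permutations per test (default 199)
#' @param n_individuals,n_locations cohort shape (default 1000 over 100
#'   locations)
#' @param alpha levels to report
#' @param degree polynomial degree for the canonical-correlation test
#' @param seed integer seed
#' @return list: `p_moran`, `p_cca` (vectors of p-values), `rates`
#'   (data.frame: alpha, rate_moran, rate_cca)
#' @export
spatial_null_calibration <- function(n_reps = 500L, n_perm = 199L,
                                     n_individuals = 1000L,
                                     n_locations = 100L,
                                     alpha = c(0.01, 0.05, 0.1),
                                     degree = 3, seed = NULL) {
  with_seed(seed, {
    lat <- stats::runif(n_locations, -30, -20)
    lon <- stats::runif(n_locations, -60, -50)
    W <- spatial_weights(data.frame(lon = lon, lat = lat))
    Xp <- .geo_poly(data.frame(lat = lat, lon = lon), degree)
    Qx <- qr.Q(qr(sweep(Xp, 2, colMeans(Xp))))
    moran_of <- function(z) { z <- z - mean(z); (drop(z %*% W %*% z)) / sum(z^2) }
    cca_of <- function(Y) {
      Yc <- sweep(Y, 2, colMeans(Y))
      sv <- svd(crossprod(Qx, qr.Q(qr(Yc))), nu = 0, nv = 0)
      sv$d[1]
    }
    p_moran <- numeric(n_reps); p_cca <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      fac <- factor(sample.int(n_locations, n_individuals, replace = TRUE),
                    levels = seq_len(n_locations))
      cnt <- as.integer(table(fac))
      keep <- cnt > 0
      q <- rdirichlet_mat(matrix(4, n_individuals, 3))
      # rowsum returns one row per present group, in level order
      sm <- function(f) rowsum(q, f) / cnt[keep]
      Wk <- W[keep, keep] / rowSums(W[keep, keep])
      mo <- function(z) { z <- z - mean(z); drop(z %*% Wk %*% z) / sum(z^2) }
      Qxk <- qr.Q(qr(sweep(Xp[keep, , drop = FALSE], 2,
                           colMeans(Xp[keep, , drop = FALSE]))))
      cc <- function(Y) {
        Yc <- sweep(Y[, 1:2], 2, colMeans(Y[, 1:2]))
        svd(crossprod(Qxk, qr.Q(qr(Yc))), nu = 0, nv = 0)$d[1]
      }
      m_obs <- mo(sm(fac)[, 3]); c_obs <- cc(sm(fac))
      m_perm <- numeric(n_perm); c_perm <- numeric(n_perm)
      for (b in seq_len(n_perm)) {
        mp <- sm(sample(fac))
        m_perm[b] <- mo(mp[, 3]); c_perm[b] <- cc(mp)
      }
      p_moran[r] <- (1 + sum(abs(m_perm) >= abs(m_obs))) / (n_perm + 1)
      p_cca[r] <- (1 + sum(abs(c_perm) >= abs(c_obs))) / (n_perm + 1)
    }
    rates <- data.frame(alpha = alpha,
                        rate_moran = vapply(alpha, function(a) mean(p_moran <= a), 0),
                        rate_cca = vapply(alpha, function(a) mean(p_cca <= a), 0))
    list(p_moran = p_moran, p_cca = p_cca, rates = rates)
  })
}
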