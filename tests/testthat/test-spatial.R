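test_that("location aggregation reduces to the obvious arithmetic", {
  q <- rbind(c(0, 1, 0), c(1, 0, 0), c(0.2, 0.3, 0.5))
  colnames(q) <- c("AFR", "EUR", "NAM")
  pg <- data.frame(birthplace_id = c("a", "a", "b"),
                   birth_lat = c(1, 1, 2), birth_lon = c(3, 3, 4))
  s <- aggregate_by_location(q, pg)
  expect_equal(s$n, c(2L, 1L))
  expect_equal(s$mean_AFR, c(0.5, 0.2))
  expect_equal(s$mean_EUR, c(0.5, 0.3))
  expect_true(is.na(s$sd_AFR[2]))       # single individual: sd undefined
  expect_false(is.na(s$sd_AFR[1]))
})

test_that("Moran's I matches a hand evaluation and the ape implementation", {
  # 4 unit-square-ish corners; like values adjacent
  coords <- data.frame(lon = c(0, 1, 0, 1), lat = c(0, 0, 1, 1))
  v <- c(1, 1, 0, 0)
  W <- spatial_weights(coords)
  z <- v - mean(v)
  I_hand <- (4 / sum(W)) * drop(z %*% W %*% z) / sum(z^2)
  expect_equal(morans_i(v, weights = W), I_hand)

  # independent oracle on random instances
  skip_if_not_installed("ape")
  set.seed(5)
  for (r in 1:5) {
    n <- sample(5:8, 1)
    coords <- data.frame(lon = runif(n, -50, -40), lat = runif(n, -20, -10))
    v <- rnorm(n)
    W <- spatial_weights(coords)
    expect_equal(morans_i(v, weights = W),
                 ape::Moran.I(v, W)$observed, tolerance = 1e-10)
  }
})

test_that("Moran's I rejects degenerate input", {
  coords <- data.frame(lon = 1:4, lat = 1:4)
  expect_error(morans_i(rep(0.5, 4), coords), "zero variance")
  expect_error(morans_i(c(1, 2), coords[1:2, ]), "at least 3")
})

test_that("permuted values concentrate Moran's I near -1/(n-1)", {
  set.seed(8)
  n <- 60
  coords <- data.frame(lon = runif(n, -60, -50), lat = runif(n, -30, -20))
  W <- spatial_weights(coords)
  v <- rnorm(n)
  Is <- replicate(400, morans_i(sample(v), weights = W))
  expect_lt(abs(mean(Is) - (-1 / (n - 1))), 0.01)
})

test_that("birthplace permutation test is deterministic and detects structure", {
  coh <- fixture_cohort()
  al <- align_panel(coh$genotypes, coh$parental_freqs)
  est <- estimate_ancestry(al$genotypes, al$panel)
  locs <- aggregate_by_location(est, coh$pheno_geo)
  stat <- function(m, xy) morans_i(m[, 1], coords = xy)
  p1 <- permutation_test_spatial(est$q[, "NAM"], coh$pheno_geo$birthplace_id,
                                 locs, stat, n_perm = 99, seed = 4)
  p2 <- permutation_test_spatial(est$q[, "NAM"], coh$pheno_geo$birthplace_id,
                                 locs, stat, n_perm = 99, seed = 4)
  expect_identical(p1$p, p2$p)
  expect_lte(p1$p, 0.02)                 # strong simulated gradient
  expect_error(permutation_test_spatial(est$q[, 1], coh$pheno_geo$birthplace_id,
                                        locs, stat, n_perm = 10), "99")
})

test_that("canonical correlation: perfect linear dependence and nesting", {
  set.seed(10)
  n <- 80
  lat <- runif(n, -30, -10); lon <- runif(n, -60, -40)
  qE <- (lat - min(lat)) / diff(range(lat)) * 0.8 + 0.1
  q <- cbind(AFR = (1 - qE) / 2, EUR = qE, NAM = (1 - qE) / 2)
  cc1 <- canonical_correlation_geo(q, data.frame(lat = lat, lon = lon), degree = 1)
  expect_gt(cc1$cancor[1], 0.999)

  q2 <- rdirichlet_mat_test(n)
  for (d in c(1, 3)) {
    cc <- canonical_correlation_geo(q2, data.frame(lat = lat, lon = lon),
                                    degree = d)
    if (d == 1) base_cc <- cc$cancor[1] else
      expect_gte(cc$cancor[1] + 1e-12, base_cc)   # nested spans
  }
})

test_that("kriging honours data exactly at nugget 0 and recovers a plane", {
  set.seed(12)
  gr <- expand.grid(lat = seq(-30, -20, length.out = 7),
                    lon = seq(-60, -50, length.out = 7))
  gr$v <- 0.2 + 0.05 * (gr$lat + 30) + 0.02 * (gr$lon + 60)
  summaries <- data.frame(birthplace_id = seq_len(nrow(gr)),
                          lat = gr$lat, lon = gr$lon, n = 5, mean_NAM = gr$v)
  pred_at_data <- krige_predict(summaries, "NAM", gr[, c("lat", "lon")])
  expect_lt(max(abs(pred_at_data - gr$v)), 1e-8)

  kg <- krige_surface(summaries, "NAM", grid_spec = list(nx = 11, ny = 11))
  expect_equal(kg$method, "ordinary_kriging")
  g <- kg$grid
  interior <- g$lat > -29 & g$lat < -21 & g$lon > -59 & g$lon < -51
  truth <- 0.2 + 0.05 * (g$lat + 30) + 0.02 * (g$lon + 60)
  expect_lt(mean(abs(g$prediction[interior] - truth[interior])), 0.01)
  expect_true(all(g$prediction >= 0 & g$prediction <= 1))
})

test_that("a constant field yields a flat surface via the IDW fallback", {
  summaries <- data.frame(birthplace_id = 1:9,
                          lat = rep(1:3, 3), lon = rep(1:3, each = 3),
                          n = 2, mean_NAM = 0.42)
  expect_warning(kg <- krige_surface(summaries, "NAM",
                                     grid_spec = list(nx = 5, ny = 5)),
                 "degenerate")
  expect_equal(kg$method, "idw")
  expect_true(all(abs(kg$grid$prediction - 0.42) < 1e-10))
})

test_that("census correlations: recovery, rank invariance, degenerate input", {
  coh <- fixture_cohort()
  locs <- aggregate_by_location(coh$true_q, coh$pheno_geo)
  res <- census_correlations(locs, min_n = 4, min_locations = 5,
                             n_perm = 199, seed = 6)
  sdrow <- res[res$analysis == "sd_vs_census" & res$component == "NAM", ]
  expect_gt(sdrow$rho, 0)                # urban_sd_effect generates this
  expect_lt(sdrow$p, 0.05)

  # monotone transform of census leaves Spearman rho unchanged
  locs2 <- locs; locs2$census_size <- log(locs2$census_size)
  res2 <- census_correlations(locs2, min_n = 4, min_locations = 5,
                              n_perm = 199, seed = 6)
  expect_equal(res2$rho, res$rho, tolerance = 1e-12)

  locs3 <- locs; locs3$census_size <- 1000
  res3 <- census_correlations(locs3)
  expect_true(res3$flagged[1])
})

test_that("altitude correlations recover the generated signs", {
  coh <- fixture_cohort()
  ac <- altitude_correlation(coh$true_q, coh$pheno_geo)
  expect_gt(ac$r[ac$component == "NAM"], 0)
  expect_lt(ac$r[ac$component == "EUR"], 0)
  # perfect linear relation
  q <- cbind(AFR = rep(0.1, 50), EUR = seq(0.1, 0.6, length.out = 50))
  q <- cbind(q, NAM = 1 - q[, 1] - q[, 2])
  pg <- data.frame(altitude = q[, "EUR"] * 1000)
  ac2 <- altitude_correlation(q, pg)
  expect_equal(ac2$r[ac2$component == "EUR"], 1, tolerance = 1e-12)
  pg0 <- data.frame(altitude = rep(5, 50))
  expect_true(all(altitude_correlation(q, pg0)$flagged))
})
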