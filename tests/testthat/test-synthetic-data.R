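test_that("parental frequency simulation honours its contracts", {
  cfg <- sim_config(n_markers = 30, seed = 1, diagnostic_fraction = 0)
  pan <- simulate_parental_freqs(cfg)
  expect_equal(dim(pan$freqs), c(30L, 3L))
  expect_true(all(pan$freqs >= 0 & pan$freqs <= 1))

  # zero-drift limit: differentiation -> 0 makes all populations identical
  cfg0 <- sim_config(n_markers = 40, seed = 2, differentiation = 1e-13,
                     diagnostic_fraction = 0)
  pan0 <- simulate_parental_freqs(cfg0)
  expect_lt(max(abs(pan0$freqs - pan0$freqs[, 1])), 1e-9)

  # diagnostic fraction 1: every marker near-fixed in exactly one population
  cfg1 <- sim_config(n_markers = 21, seed = 3, diagnostic_fraction = 1)
  pan1 <- simulate_parental_freqs(cfg1)
  n_diag <- apply(pan1$freqs, 1, function(f) sum(f >= 0.95))
  other_low <- apply(pan1$freqs, 1, function(f) all(sort(f)[1:2] <= 0.05))
  expect_true(all(n_diag == 1))
  expect_true(all(other_low))
})

test_that("cohort generation is deterministic and q lies on the simplex", {
  cfg <- sim_config(n_individuals = 80, n_markers = 20, seed = 11)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$true_q, c2$true_q)
  expect_identical(unclass(c1$genotypes), unclass(c2$genotypes))
  expect_identical(c1$pheno_geo, c2$pheno_geo)
  expect_identical(c1$perception, c2$perception)
  expect_simplex(c1$true_q, tol = 1e-9)
  expect_true(all(unclass(c1$genotypes) %in% c(0L, 1L, 2L)))
})

test_that("genotypes follow the binomial admixture model at a q corner", {
  coh <- fixture_corner_cohort(n = 600, m = 40, pop = "AFR", seed = 5)
  expect_true(all(coh$true_q[, "AFR"] > 0.995))
  emp <- colMeans(unclass(coh$genotypes)) / 2
  fa <- coh$parental_freqs$freqs[, "AFR"]
  # binomial sampling error at n = 600, 2 draws each
  tol <- 4 * sqrt(pmax(fa * (1 - fa), 0.002) / (2 * 600))
  expect_true(all(abs(emp - fa) < tol))
})

test_that("mean ancestry per location tracks the configured spatial surface", {
  cfg <- sim_config(n_individuals = 2000, n_markers = 5, seed = 21,
                    concentration = 60, urban_sd_effect = 0,
                    spatial_gradient = c(0, -1.0, 1.2),
                    countries = list(One = list(mean = c(0.1, 0.5, 0.4),
                                                box = c(-30, -10, -60, -50),
                                                n_frac = 1)))
  coh <- simulate_cohort(cfg)
  loc <- aggregate_by_location(coh$true_q, coh$pheno_geo)
  lat_s <- (loc$lat - (-20)) / 10
  eta <- sweep(outer(lat_s, c(0, -1.0, 1.2)), 2, log(c(0.1, 0.5, 0.4)), `+`)
  expected <- exp(eta) / rowSums(exp(eta))
  big <- loc$n >= 30
  expect_gt(sum(big), 5)
  expect_lt(mean(abs(loc$mean_NAM[big] - expected[big, 3])), 0.04)
})

test_that("null effect sizes yield no ancestry signal in phenotypes", {
  cfg <- sim_config(n_individuals = 900, n_markers = 10, seed = 31,
                    effect_sizes = default_effect_sizes(null_ancestry = TRUE))
  coh <- simulate_cohort(cfg)
  des <- ancestry_design(coh$true_q, coh$pheno_geo)
  dr <- delta_r2(des, "melanin_index")
  expect_lt(dr$delta_r2, 0.02)
})

test_that("undistorted noiseless perception always bands the true ancestry", {
  cfg <- sim_config(n_individuals = 300, n_markers = 10, seed = 41,
                    perception_distortion = list(weight = 0, noise_sd = 0))
  coh <- simulate_cohort(cfg)
  for (k in c("AFR", "EUR", "NAM")) {
    b <- bias_records(coh$true_q, coh$perception)
    expect_true(all(b[[paste0("bias_", k)]] == 0),
                label = sprintf("zero bias for %s", k))
  }
})

test_that("missingness is injected at the configured rate and only there", {
  cfg <- sim_config(n_individuals = 500, n_markers = 40, seed = 51,
                    missing_rate = 0.1)
  coh <- simulate_cohort(cfg)
  rate <- mean(is.na(unclass(coh$genotypes)))
  expect_gt(rate, 0.08); expect_lt(rate, 0.12)
  cfg0 <- sim_config(n_individuals = 100, n_markers = 20, seed = 52)
  expect_false(anyNA(unclass(simulate_cohort(cfg0)$genotypes)))
})

test_that("cohort writers round-trip through the documented formats", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_individuals = 30, n_markers = 12, seed = 61,
                    missing_rate = 0.05)
  coh <- simulate_cohort(cfg)
  write_cohort(coh, dir)
  g_tsv <- read_genotypes(file.path(dir, "genotypes.tsv"))
  expect_equal(unclass(g_tsv), unclass(coh$genotypes))
  g_vcf <- read_genotypes(file.path(dir, "genotypes.vcf"))
  expect_equal(unclass(g_vcf), unclass(coh$genotypes))
  pan <- read_panel_csv(file.path(dir, "parental_freqs.csv"))
  expect_equal(pan$freqs, coh$parental_freqs$freqs, tolerance = 1e-6)
})

test_that("yaml configuration mirrors sim_config arguments", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_individuals: 40", "n_markers: 15", "seed: 9",
               "perception_distortion:", "  weight: 0.0", "  noise_sd: 0.0",
               "countries:", "  Brazil:", "    n_frac: 1.0"), path)
  cfg <- sim_config_from_yaml(path)
  expect_equal(cfg$n_individuals, 40)
  expect_equal(cfg$n_markers, 15)
  expect_equal(cfg$perception_distortion$weight, 0)
  expect_equal(names(cfg$countries), "Brazil")
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$true_q), 40)
})

test_that("configuration errors are caught", {
  expect_error(sim_config(n_individuals = 0), "positive")
  expect_error(sim_config(differentiation = 1.2), "differentiation")
  expect_error(sim_config(concentration = -1), "alpha")
  cfg <- sim_config(n_markers = 10, seed = 1)
  pan <- simulate_parental_freqs(sim_config(n_markers = 11, seed = 1))
  expect_error(simulate_cohort(cfg, pan), "markers")
})
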