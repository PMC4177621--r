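test_that("band intervals follow the 20% bracket convention", {
  expect_equal(unname(band_interval(1)), matrix(c(0, 0.2), 1))
  expect_equal(unname(band_interval(5)), matrix(c(0.8, 1.0), 1))
  expect_equal(unname(band_interval(3)), matrix(c(0.4, 0.6), 1))
  expect_error(band_interval(6), "1..5")
  expect_error(band_interval(0), "1..5")
})

test_that("the bias statistic reproduces its worked examples exactly", {
  expect_identical(perception_bias(0.50, 3), 0)        # inside [0.4, 0.6]
  expect_equal(perception_bias(0.75, 1), -0.55, tolerance = 1e-12)  # 0.2 - 0.75
  expect_equal(perception_bias(0.10, 5), 0.70, tolerance = 1e-12)   # 0.8 - 0.10
  expect_error(perception_bias(1.2, 3), "\\[0, 1\\]")
})

test_that("bias is zero exactly on the closed band and grows away from it", {
  for (band in 1:5) {
    iv <- band_interval(band)
    qs <- seq(0, 1, by = 0.005)
    b <- perception_bias(qs, rep(band, length(qs)))
    inside <- qs >= iv[, "lo"] & qs <= iv[, "hi"]
    expect_true(all(b[inside] == 0))
    expect_true(all(b[!inside] != 0))
    expect_true(all(abs(b) <= 1))
    # |bias| strictly increasing moving away from the interval
    below <- qs < iv[, "lo"]
    if (any(below)) expect_true(all(diff(abs(b[below])) < 0))
    above <- qs > iv[, "hi"]
    if (any(above)) expect_true(all(diff(abs(b[above])) > 0))
  }
})

test_that("bias is antisymmetric under mirroring q and band", {
  grid_q <- seq(0, 1, by = 0.01)
  for (band in 1:5) {
    b1 <- perception_bias(grid_q, rep(band, length(grid_q)))
    b2 <- perception_bias(1 - grid_q, rep(6L - band, length(grid_q)))
    expect_equal(b2, -b1, tolerance = 1e-12)
  }
})

test_that("the midpoint variant differs only off-centre", {
  expect_equal(perception_bias_midpoint(0.5, 3), 0)
  expect_equal(perception_bias_midpoint(0.75, 1), 0.1 - 0.75)
  rec <- bias_records(cbind(AFR = 0.5, EUR = 0.3, NAM = 0.2),
                      data.frame(sample_id = "a", band_AFR = 3,
                                 band_EUR = 2, band_NAM = 1),
                      method = "midpoint")
  expect_equal(rec$bias_AFR, 0)
  expect_equal(rec$bias_EUR, 0.0)        # midpoint 0.3 equals q
})

test_that("band correlation hits the discretization cap for exact banding", {
  set.seed(31)
  q <- runif(4000)
  band <- pmax(1, ceiling(q * 5))
  # oracle: the attainable correlation is that of q with its own banding
  cap <- cor(band, q)
  bc <- band_correlation(band, q)
  expect_equal(bc$r, cap)
  expect_gt(bc$r, 0.95)
  # independent bands carry no signal
  bc0 <- band_correlation(sample(band), q)
  expect_lt(abs(bc0$r), 0.05)
  expect_true(band_correlation(rep(2L, 10), runif(10))$flagged)
})

test_that("a distortion generator lands band-vs-q correlation in the reported regime", {
  cfg <- sim_config(n_individuals = 2500, n_markers = 5, seed = 41,
                    perception_distortion = list(weight = 0.45, noise_sd = 0.7))
  coh <- simulate_cohort(cfg)
  for (k in c("EUR", "NAM")) {
    r <- band_correlation(coh$perception[[paste0("band_", k)]],
                          coh$true_q[, k])$r
    expect_gt(r, 0.25); expect_lt(r, 0.6)
  }
})

test_that("bias regression recovers the direction of the distortion", {
  cfg <- sim_config(n_individuals = 2000, n_markers = 30, seed = 43)
  coh <- simulate_cohort(cfg)
  al <- align_panel(coh$genotypes, coh$parental_freqs)
  est <- estimate_ancestry(al$genotypes, al$panel)
  des <- ancestry_design(est, coh$pheno_geo)
  rec <- bias_records(est, coh$perception)
  fits <- fit_bias_model(rec, des, phenotypes = "melanin_index")
  coef_of <- function(k) {
    cf <- fits[[k]]$coefficients
    cf[cf$term == "melanin_index", "estimate"]
  }
  # low melanin inflates the EUR band: negative melanin coefficient for
  # the EUR bias, positive for AFR and NAM
  expect_lt(coef_of("EUR"), 0)
  expect_gt(coef_of("AFR"), 0)
  expect_gt(coef_of("NAM"), 0)
})

test_that("accurate perception yields a null bias regression", {
  cfg <- sim_config(n_individuals = 1200, n_markers = 5, seed = 47,
                    perception_distortion = list(weight = 0, noise_sd = 0))
  coh <- simulate_cohort(cfg)
  rec <- bias_records(coh$true_q, coh$perception)
  expect_true(all(rec$bias_EUR == 0))
  des <- ancestry_design(coh$true_q, coh$pheno_geo)
  fits <- fit_bias_model(rec, des)
  cf <- fits$EUR$coefficients
  expect_lt(abs(cf$estimate[cf$term == "(Intercept)"]), 1e-12)
  expect_true(is.nan(fits$EUR$r2) || fits$EUR$r2 < 1e-10)  # no variance left
})

test_that("reference pyramid calibration satisfies both beta constraints", {
  rp <- reference_pyramid(20000, coverage = 0.75, seed = 53)
  cal <- rp$calibration
  expect_true(all(cal$residual < 1e-4))
  for (b in 1:5) {
    med <- qbeta(0.5, cal$alpha[b], cal$beta[b])
    expect_equal(med, cal$centre[b], tolerance = 1e-4)
    lo <- max(cal$centre[b] - 0.1, 0); hi <- min(cal$centre[b] + 0.1, 1)
    mass <- pbeta(hi, cal$alpha[b], cal$beta[b]) -
      pbeta(lo, cal$alpha[b], cal$beta[b])
    expect_equal(mass, 0.75, tolerance = 1e-4)
  }
  expect_true(all(abs(cal$empirical_mass - 0.75) < 0.02))
  # coverage near 1: almost the whole sample inside the band interval
  rp99 <- reference_pyramid(5000, coverage = 0.99, seed = 54)
  expect_true(all(rp99$calibration$empirical_mass > 0.97))
  expect_error(reference_pyramid(10, coverage = 1.2), "coverage")
  expect_error(reference_pyramid(0), "n must be")
})
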