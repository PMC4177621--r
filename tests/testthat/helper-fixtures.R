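# Shared fixtures built in code. Small cohorts reused across test files.

fixture_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      cfg <- sim_config(n_individuals = 400, n_markers = 60, seed = 101)
      memo <<- simulate_cohort(cfg)
    }
    memo
  }
})

# cohort whose individuals are (almost) pure members of one population:
# one stratum whose Dirichlet mean sits at the AFR corner, huge concentration
fixture_corner_cohort <- function(n = 400, m = 50, pop = "AFR", seed = 7) {
  mean_q <- c(AFR = 1e-4, EUR = 1e-4, NAM = 1e-4)
  mean_q[pop] <- 1 - 2e-4
  cfg <- sim_config(
    n_individuals = n, n_markers = m, seed = seed,
    concentration = 1e6, spatial_gradient = c(0, 0, 0),
    urban_sd_effect = 0,
    countries = list(One = list(mean = unname(mean_q),
                                box = c(-10, 0, -60, -50), n_frac = 1)))
  simulate_cohort(cfg)
}

# diagnostic 3-marker panel: marker k has frequency 1 in population k, 0 elsewhere
fixture_diagnostic_panel <- function() {
  f <- diag(3)
  parental_panel(f, marker_ids = c("d1", "d2", "d3"),
                 population_labels = c("AFR", "EUR", "NAM"))
}

expect_simplex <- function(q, tol = 1e-8) {
  expect_true(all(abs(rowSums(q) - 1) < tol))
  expect_true(all(q >= -tol & q <= 1 + tol))
}

rdirichlet_mat_test <- function(n, alpha = c(2, 2, 2)) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)), n)
  colnames(g) <- c("AFR", "EUR", "NAM")[seq_along(alpha)]
  g / rowSums(g)
}
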