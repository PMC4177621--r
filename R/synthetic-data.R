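# synthetic_data: cohort generator emulating the statistical structure of a
# three-way admixed Latin American study sample -- spatially structured
# ancestry, ancestry-driven phenotypes, banded self-perception, wealth items
# and 3D facial landmarks -- so every downstream stage is testable without
# restricted cohort data.

# Country strata: Dirichlet mean ancestry (AFR/EUR/NAM) follows the median
# admixture profile of the five sampled countries; bounding boxes are coarse
# lat/lon rectangles used only to lay out synthetic birthplaces.
.country_defaults <- function() {
  list(
    Brazil   = list(mean = c(0.09, 0.82, 0.09), box = c(-30, -5, -55, -40), n_frac = 0.22),
    Chile    = list(mean = c(0.05, 0.48, 0.47), box = c(-40, -18, -72, -68), n_frac = 0.21),
    Colombia = list(mean = c(0.11, 0.60, 0.29), box = c(0, 10, -77, -70), n_frac = 0.22),
    Mexico   = list(mean = c(0.05, 0.38, 0.57), box = c(15, 30, -110, -90), n_frac = 0.22),
    Peru     = list(mean = c(0.02, 0.30, 0.68), box = c(-17, -3, -80, -70), n_frac = 0.13)
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults emulate a
#' five-country, three-way admixed sample: ~30 ancestry-informative markers,
#' country-specific Dirichlet ancestry with a smooth spatial gradient,
#' continuous/ordinal/binary phenotypes linear in European and African
#' ancestry, and 5-band self-perceived ancestry distorted by pigmentation.
#'
#' @param n_individuals cohort size
#' @param n_markers number of biallelic markers in the parental panel
#' @param K number of ancestral populations (AFR/EUR/NAM labels for K = 3)
#' @param differentiation per-population Balding-Nichols drift parameter(s)
#'   in (0,1); scalar recycled to K
#' @param diagnostic_fraction fraction of markers forced near-diagnostic
#'   (frequency >= 0.95 in one population, <= 0.05 elsewhere)
#' @param concentration Dirichlet concentration of individual ancestry about
#'   its stratum/location mean (smaller = more variable individuals)
#' @param countries named list of per-country strata (mean ancestry, lat/lon
#'   box, sampling fraction); see defaults
#' @param n_locations_per_country birthplaces laid out per country
#' @param spatial_gradient K-vector of logit slopes applied to standardized
#'   latitude (per country), shifting mean ancestry smoothly in space;
#'   0 gives no spatial structure
#' @param urban_sd_effect strength with which larger census size inflates
#'   within-location ancestry dispersion (0 disables)
#' @param effect_sizes named list of per-trait generative models; see
#'   [default_effect_sizes()]
#' @param perception_distortion list with `weight` (how strongly standardized
#'   melanin shifts the self-perception latent away from true ancestry;
#'   positive for AFR/NAM, negative for EUR) and `noise_sd`
#' @param missing_rate genotype missingness injected uniformly at random
#' @param n_landmarks facial landmarks per individual (3D)
#' @param seed integer seed from which all randomness flows
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_individuals = 600,
                       n_markers = 30,
                       K = 3,
                       differentiation = 0.15,
                       diagnostic_fraction = 0.2,
                       concentration = 12,
                       countries = .country_defaults(),
                       n_locations_per_country = 20,
                       spatial_gradient = c(-0.5, -1.0, 1.2),
                       urban_sd_effect = 0.5,
                       effect_sizes = default_effect_sizes(),
                       perception_distortion = list(weight = 0.12, noise_sd = 0.06),
                       missing_rate = 0,
                       n_landmarks = 36,
                       seed = 1L) {
  if (n_individuals < 1 || n_markers < 1)
    stop_config("n_individuals and n_markers must be positive")
  if (K < 2) stop_config("K must be >= 2")
  differentiation <- rep_len(differentiation, K)
  if (any(differentiation <= 0 | differentiation >= 1))
    stop_config("differentiation must lie in (0,1)")
  if (concentration <= 0) stop_config("concentration (dirichlet alpha scale) must be > 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_config("missing_rate must be in [0,1)")
  pops <- if (K == 3) c("AFR", "EUR", "NAM") else paste0("POP", seq_len(K))
  structure(list(n_individuals = n_individuals, n_markers = n_markers, K = K,
                 populations = pops,
                 differentiation = differentiation,
                 diagnostic_fraction = diagnostic_fraction,
                 concentration = concentration,
                 countries = countries,
                 n_locations_per_country = n_locations_per_country,
                 spatial_gradient = rep_len(spatial_gradient, K),
                 urban_sd_effect = urban_sd_effect,
                 effect_sizes = effect_sizes,
                 perception_distortion = perception_distortion,
                 missing_rate = missing_rate,
                 n_landmarks = n_landmarks,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default phenotype generative models
#'
#' Each entry defines one trait: its type, intercept, European and African
#' ancestry effects (Native American ancestry is the baseline), covariate
#' effects and noise. Effect magnitudes mirror the characteristic regime of
#' admixture studies of physical appearance: pigmentation strongly
#' ancestry-driven, anthropometrics weakly so. Melanin index is on the
#' reflectometry scale, height in cm.
#'
#' @param null_ancestry if TRUE, zero out every ancestry effect (null
#'   generator for calibration tests)
#' @return named list of trait specifications
#' @export
default_effect_sizes <- function(null_ancestry = FALSE) {
  es <- list(
    melanin_index = list(type = "continuous", intercept = 38, beta_eur = -10,
                         beta_afr = 12, beta_age = 0, beta_sex = 0, sd = 4),
    height = list(type = "continuous", intercept = 163, beta_eur = 7.3,
                  beta_afr = 8.1, beta_age = -0.1, beta_sex = 12, sd = 6.5),
    weight = list(type = "continuous", intercept = 62, beta_eur = 0.4,
                  beta_afr = 1.0, beta_age = 0.3, beta_sex = 14, sd = 10),
    eye_color = list(type = "ordinal", intercept = 0, beta_eur = -1.26,
                     beta_afr = 0.24, beta_age = 0, beta_sex = 0, sd = 0.6,
                     levels = 5),
    hair_shape = list(type = "ordinal", intercept = 0, beta_eur = 0.47,
                      beta_afr = 2.41, beta_age = 0, beta_sex = 0, sd = 0.8,
                      levels = 4),
    eye_fold = list(type = "ordinal", intercept = 0, beta_eur = -0.37,
                    beta_afr = -0.37, beta_age = 0, beta_sex = 0, sd = 0.5,
                    levels = 3, first_level = 0),
    balding = list(type = "binary", intercept = -2.2, beta_eur = 1.2,
                   beta_afr = 1.5, beta_age = 0.05, beta_sex = 0)
  )
  if (null_ancestry)
    es <- lapply(es, function(e) { e$beta_eur <- 0; e$beta_afr <- 0; e })
  es
}

#' Simulate a parental allele-frequency panel
#'
#' Balding-Nichols model: each marker has an ancestral frequency p drawn
#' Uniform(0.1, 0.9); population k's frequency is Beta with mean p and
#' variance F_k p (1-p), i.e. shape p(1-F)/F, (1-p)(1-F)/F. A configurable
#' fraction of markers is made near-diagnostic (>= 0.95 in one population,
#' <= 0.05 elsewhere), emulating a panel enriched for ancestry information.
#'
#' @param config a [sim_config()]
#' @return a [parental_panel()]
#' @export
simulate_parental_freqs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    M <- config$n_markers; K <- config$K
    p0 <- stats::runif(M, 0.1, 0.9)
    f <- matrix(NA_real_, M, K)
    for (k in seq_len(K)) {
      Fk <- config$differentiation[k]
      if (Fk < 1e-12) { f[, k] <- p0; next }
      f[, k] <- stats::rbeta(M, p0 * (1 - Fk) / Fk, (1 - p0) * (1 - Fk) / Fk)
    }
    n_diag <- round(config$diagnostic_fraction * M)
    if (n_diag > 0) {
      idx <- seq_len(n_diag)
      owner <- rep_len(seq_len(K), n_diag)
      for (i in seq_along(idx)) {
        f[idx[i], ] <- stats::runif(K, 0, 0.05)
        f[idx[i], owner[i]] <- stats::runif(1, 0.95, 1)
      }
    }
    parental_panel(f, marker_ids = sprintf("rs%05d", seq_len(M)),
                   population_labels = config$populations)
  })
}

# lay out synthetic birthplaces: per-country locations with census sizes
# (log-normal, heavy-tailed as real settlement sizes are) and altitude tied
# to the same latitude score that drives the ancestry gradient
.simulate_locations <- function(config) {
  out <- list()
  for (cn in names(config$countries)) {
    cc <- config$countries[[cn]]
    L <- config$n_locations_per_country
    lat <- stats::runif(L, cc$box[1], cc$box[2])
    lon <- stats::runif(L, cc$box[3], cc$box[4])
    census <- round(stats::rlnorm(L, meanlog = 10, sdlog = 1.6))
    lat_s <- (lat - mean(c(cc$box[1], cc$box[2]))) / (diff(cc$box[1:2]) / 2)
    altitude <- pmax(0, 1200 + 900 * lat_s + stats::rnorm(L, 0, 220))
    out[[cn]] <- data.frame(
      birthplace_id = sprintf("%s_%02d", cn, seq_len(L)),
      country = cn, lat = lat, lon = lon, lat_s = lat_s,
      census_size = census, altitude = altitude,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Simulate a full synthetic cohort
#'
#' Individuals are assigned to countries (by stratum fractions) and to
#' birthplaces within country (sampling probability increasing with census
#' size). Individual ancestry q is Dirichlet about a location mean: the
#' country's mean ancestry shifted on the logit scale by
#' `spatial_gradient * lat_s`, with Dirichlet concentration shrinking as
#' census size grows (urban samples are more heterogeneous). Genotype at
#' marker j is Binomial(2, sum_k q_k f_jk). Continuous phenotypes are linear
#' in (qEUR, qAFR) plus covariates and Gaussian noise; ordinal traits
#' threshold a latent continuous variable; binary traits use a logistic
#' link. The self-perception band for each continent is the 20%-band of
#' q_k + distortion * standardized melanin (+ for AFR/NAM, - for EUR) plus
#' noise, clipped to [0,1]; boundary ties go to the lower band.
#'
#' @param config a [sim_config()]
#' @param panel a [parental_panel()]; defaults to
#'   `simulate_parental_freqs(config)`
#' @return object of class `synthetic_cohort`: list with `genotypes`,
#'   `true_q`, `pheno_geo`, `perception`, `parental_freqs`, `locations`,
#'   `assets`, `landmarks`
#' @export
simulate_cohort <- function(config, panel = simulate_parental_freqs(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "parental_panel"))
  if (nrow(panel$freqs) != config$n_markers)
    stop_config("panel has %d markers but config says %d",
                nrow(panel$freqs), config$n_markers)
  if (ncol(panel$freqs) != config$K)
    stop_config("panel has %d populations but config says K = %d",
                ncol(panel$freqs), config$K)
  with_seed(config$seed + 1L, {
    N <- config$n_individuals; K <- config$K
    loc <- .simulate_locations(config)

    frac <- vapply(config$countries, `[[`, numeric(1), "n_frac")
    country <- sample(names(config$countries), N, replace = TRUE,
                      prob = frac / sum(frac))
    loc_idx <- integer(N)
    for (cn in names(config$countries)) {
      ii <- which(country == cn)
      cand <- which(loc$country == cn)
      loc_idx[ii] <- sample(cand, length(ii), replace = TRUE,
                            prob = sqrt(loc$census_size[cand]))
    }

    # location mean ancestry: country mean logit-shifted by the gradient
    cmeans <- t(vapply(config$countries, `[[`, numeric(3), "mean"))
    base <- log(pmax(cmeans[match(loc$country, names(config$countries)), ,
                            drop = FALSE], 1e-3))
    shift <- outer(loc$lat_s, config$spatial_gradient)
    eta <- base + shift
    mloc <- exp(eta) / rowSums(exp(eta))

    # concentration shrinks with census size => larger sd_q in big places
    czs <- scale(log(loc$census_size))[, 1]
    conc_loc <- config$concentration * exp(-config$urban_sd_effect * czs)

    alpha <- mloc[loc_idx, , drop = FALSE] * conc_loc[loc_idx]
    q <- rdirichlet_mat(alpha)
    colnames(q) <- config$populations
    sample_ids <- sprintf("ind%05d", seq_len(N))
    rownames(q) <- sample_ids

    # genotypes: binomial mixture of parental frequencies
    P <- q %*% t(panel$freqs)                      # N x M expected dosage/2
    G <- matrix(stats::rbinom(length(P), 2L, pmin(pmax(P, 0), 1)),
                nrow = N, dimnames = list(sample_ids, panel$marker_ids))
    if (config$missing_rate > 0) {
      drop <- stats::runif(length(G)) < config$missing_rate
      G[drop] <- NA_integer_
    }

    # covariates
    age <- round(stats::runif(N, 18, 45))
    sex <- sample(c(0L, 1L), N, replace = TRUE)    # 1 = male
    education <- sample(1:3, N, replace = TRUE, prob = c(0.25, 0.4, 0.35))
    wealth_latent <- stats::rnorm(N, 0.8 * q[, "EUR"], 1)
    wealth_decile <- as.integer(stats::ave(wealth_latent, country,
      FUN = function(z) ceiling(10 * (rank(z, ties.method = "first") / (length(z) + 1)))))

    pg <- data.frame(sample_id = sample_ids, country = country, age = age,
                     sex = sex, education = education,
                     wealth_decile = wealth_decile,
                     birthplace_id = loc$birthplace_id[loc_idx],
                     birth_lat = loc$lat[loc_idx], birth_lon = loc$lon[loc_idx],
                     altitude = loc$altitude[loc_idx],
                     census_size = loc$census_size[loc_idx],
                     stringsAsFactors = FALSE)

    qE <- q[, "EUR"]; qA <- q[, "AFR"]
    for (tn in names(config$effect_sizes)) {
      e <- config$effect_sizes[[tn]]
      lin <- e$intercept + e$beta_eur * qE + e$beta_afr * qA +
        e$beta_age * age + e$beta_sex * sex
      if (e$type == "continuous") {
        pg[[tn]] <- lin + stats::rnorm(N, 0, e$sd)
      } else if (e$type == "ordinal") {
        latent <- lin + stats::rnorm(N, 0, e$sd)
        br <- stats::quantile(latent, probs = seq_len(e$levels - 1) / e$levels)
        first <- if (is.null(e$first_level)) 1L else as.integer(e$first_level)
        pg[[tn]] <- first + as.integer(cut(latent, c(-Inf, br, Inf))) - 1L
      } else if (e$type == "binary") {
        pg[[tn]] <- stats::rbinom(N, 1L, stats::plogis(lin))
      } else stop_config("unknown trait type '%s'", e$type)
    }
    pg$BMI <- pg$weight / (pg$height / 100)^2

    # self-perception: latent = q + distortion * melanin_std (+AFR/+NAM/-EUR)
    pd <- config$perception_distortion
    mel_std <- if ("melanin_index" %in% names(pg))
      as.numeric(scale(pg$melanin_index)) else rep(0, N)
    sign_k <- c(AFR = 1, EUR = -1, NAM = 1)[config$populations]
    sign_k[is.na(sign_k)] <- 0
    perception <- data.frame(sample_id = sample_ids)
    for (k in seq_len(K)) {
      latent <- q[, k] + pd$weight * sign_k[k] * mel_std +
        stats::rnorm(N, 0, pd$noise_sd)
      latent <- pmin(pmax(latent, 0), 1)
      perception[[paste0("band_", config$populations[k])]] <-
        pmax(1L, as.integer(ceiling(latent * 5)))
    }

    assets <- .simulate_assets(wealth_latent, country)
    landmarks <- .simulate_landmarks(config, q, sample_ids)

    structure(list(genotypes = genotype_matrix(G),
                   true_q = q, pheno_geo = pg, perception = perception,
                   parental_freqs = panel, locations = loc,
                   assets = assets, landmarks = landmarks,
                   config = config),
              class = "synthetic_cohort")
  })
}

# ordinal household-asset items driven by one latent wealth factor
.simulate_assets <- function(wealth_latent, country) {
  n <- length(wealth_latent)
  item <- function(loading, n_levels, noise = 1) {
    z <- loading * wealth_latent + stats::rnorm(n, 0, noise)
    as.integer(cut(z, stats::quantile(z, seq(0, 1, length.out = n_levels + 1)),
                   include.lowest = TRUE))
  }
  data.frame(sample_id = sprintf("ind%05d", seq_len(n)), country = country,
             home_owned = item(0.9, 2), bathrooms = item(1.0, 4),
             cars = item(0.8, 3), tvs = item(0.7, 4),
             appliances = item(0.9, 4), domestic_service = item(0.6, 2),
             stringsAsFactors = FALSE)
}

# raw 3D facial landmarks: a fixed template, an ancestry deformation axis,
# individual shape noise, then a random similarity transform per individual
.simulate_landmarks <- function(config, q, sample_ids, ancestry_effect = 0.25,
                                shape_sd = 0.02) {
  L <- config$n_landmarks
  if (is.null(L) || L < 3) return(NULL)
  template <- matrix(stats::rnorm(L * 3), L, 3)
  template <- sweep(template, 2, colMeans(template))
  template <- template / sqrt(sum(template^2))
  deform <- matrix(stats::rnorm(L * 3, 0, 1), L, 3)
  deform <- deform / sqrt(sum(deform^2))
  N <- nrow(q)
  qE <- if ("EUR" %in% colnames(q)) q[, "EUR"] else q[, 1]
  coords <- array(NA_real_, c(N, L, 3),
                  dimnames = list(sample_ids, sprintf("lm%02d", seq_len(L)),
                                  c("x", "y", "z")))
  for (i in seq_len(N)) {
    shp <- template + ancestry_effect * (qE[i] - 0.5) * deform +
      matrix(stats::rnorm(L * 3, 0, shape_sd), L, 3)
    th <- stats::runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
    Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    s <- exp(stats::rnorm(1, log(100), 0.1))     # arbitrary camera units
    t <- stats::rnorm(3, 0, 5)
    coords[i, , ] <- sweep(s * shp %*% (Rz %*% Ry %*% Rx), 2, -t)
  }
  landmark_set(coords)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d individuals, %d markers, %d countries\n",
              nrow(x$true_q), ncol(x$genotypes),
              length(unique(x$pheno_geo$country))))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits genotypes as VCF and TSV, the parental panel, metadata/phenotypes,
#' perception bands, asset items and the truth table as CSV.
#'
#' @param cohort a [simulate_cohort()] result
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"),
                      panel = cohort$parental_freqs)
  write_genotypes_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_panel_csv(cohort$parental_freqs, file.path(dir, "parental_freqs.csv"))
  utils::write.csv(cohort$pheno_geo, file.path(dir, "pheno_geo.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$perception, file.path(dir, "perception.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$assets, file.path(dir, "assets.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(sample_id = rownames(cohort$true_q),
                              cohort$true_q),
                   file.path(dir, "true_q.csv"), row.names = FALSE)
  if (!is.null(cohort$landmarks))
    write_landmarks_csv(cohort$landmarks, file.path(dir, "landmarks.csv"))
  invisible(dir)
}

#' Build a simulation configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [sim_config()]; nested sections
#' (`countries`, `effect_sizes`, `perception_distortion`) map to the
#' corresponding list arguments.
#'
#' @param path YAML file
#' @return a [sim_config()]
#' @export
sim_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  base <- .country_defaults()
  if (!is.null(y$countries)) {
    for (cn in names(y$countries)) {
      for (f in names(y$countries[[cn]]))
        base[[cn]][[f]] <- unlist(y$countries[[cn]][[f]])
    }
    base <- base[intersect(names(base), names(y$countries))]
    y$countries <- base
  }
  args <- y[intersect(names(y), names(formals(sim_config)))]
  do.call(sim_config, args)
}
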