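# Synthetic cohorts with the statistical structure the pipeline assumes:
# modular streamline-count connectomes, band-limited BOLD with plantable
# per-region band energies, and linear outcome models with known effects.

#' Desikan-Killiany cortical region labels (66 regions)
#'
#' The 33 cortical parcel names per hemisphere (`lh_`/`rh_` prefixes) used
#' to label synthetic connectomes at the default 66-region resolution.
#'
#' @return Character vector of length 66.
#' @export
desikan_killiany_labels <- function() {
  base <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal"
  )
  c(paste0("lh_", base), paste0("rh_", base))
}

#' Synthetic cohort configuration
#'
#' Bundles the generator parameters. Defaults mirror the study conditions
#' the pipeline targets: 66 cortical regions, 154 timepoints at TR 2 s
#' (145 analysis-ready frames after the 18 s trim), K = 10 modes per band,
#' ages ~ Normal(50, 11^2) truncated at 20 years, and serum NfL a linear
#' function of age (0.266 pg/mL per year) plus planted band-energy effects
#' and Gaussian noise.
#'
#' @param n_subjects Cohort size.
#' @param n_regions,n_timepoints,tr Imaging dimensions (raw timepoints; the
#'   generator emits analysis-ready series of length
#'   `n_timepoints - floor(18 / tr)`).
#' @param n_modules,within_mean,between_mean Modular connectome model:
#'   module count and Poisson means for within-/between-module streamline
#'   counts.
#' @param k_band Modes per graph-frequency band.
#' @param planted Tibble `region`, `band`, `beta`: features with a planted
#'   linear effect (per standardized feature unit) on serum NfL.
#' @param energy_mean,energy_sd Across-subject distribution of the planted
#'   features' band energies (arbitrary units of z-scored BOLD).
#' @param sigma_low,sigma_high,bold_noise_sd Spectral-coefficient scales per
#'   band and additive region-space white-noise SD.
#' @param age_mean,age_sd,age_min Age model (years).
#' @param beta0,beta_age,nfl_sd Serum NfL model (pg/mL): intercept, age
#'   slope, and residual SD; NfL is floored at 0.1 pg/mL.
#' @param cohort Cohort label carried into the records.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 20, n_regions = 66,
                         n_timepoints = 154, tr = 2,
                         n_modules = 4, within_mean = 20, between_mean = 2,
                         k_band = 10,
                         planted = tibble(region = character(),
                                          band = character(),
                                          beta = numeric()),
                         energy_mean = 5, energy_sd = 1,
                         sigma_low = 1, sigma_high = 1, bold_noise_sd = 0,
                         age_mean = 50, age_sd = 11, age_min = 20,
                         beta0 = 10, beta_age = 0.266, nfl_sd = 2,
                         cohort = "HC") {
  stopifnot(energy_sd > 0, age_sd > 0, nfl_sd >= 0)
  cfg <- as.list(environment())
  structure(cfg, class = "synth_config")
}

#' Generate a modular random connectome
#'
#' Block-structured symmetric streamline-count matrix: Poisson draws with
#' mean `within_mean` inside modules and `between_mean` between them, zero
#' diagonal. Resamples (up to `max_retries` times) until the graph is
#' connected.
#'
#' @param n_regions Number of regions.
#' @param n_modules,within_mean,between_mean Block model parameters.
#' @param labels Region labels (defaults to [desikan_killiany_labels()] at
#'   66 regions, generic names otherwise).
#' @param subject_id Identifier.
#' @param seed Optional integer seed; omitted, the current RNG stream is
#'   used (as when called from [gen_cohort()]).
#' @param max_retries Connectivity resampling budget.
#' @return A validated `connectome`.
#' @export
gen_connectome <- function(n_regions = 66, n_modules = 4, within_mean = 20,
                           between_mean = 2, labels = NULL,
                           subject_id = "sim", seed = NULL,
                           max_retries = 10) {
  if (is.null(labels)) {
    labels <- if (n_regions == 66) desikan_killiany_labels() else
      sprintf("region_%02d", seq_len(n_regions))
  }
  run <- function() {
    membership <- sort(rep_len(seq_len(n_modules), n_regions))
    mu <- ifelse(outer(membership, membership, "=="),
                 within_mean, between_mean)
    a <- matrix(0, n_regions, n_regions)
    ut <- upper.tri(a)
    a[ut] <- rpois(sum(ut), mu[ut])
    a <- a + t(a)
    for (try in seq_len(max_retries)) {
      g <- igraph::graph_from_adjacency_matrix(a > 0, mode = "undirected")
      if (igraph::is_connected(g)) {
        return(validate_connectome(a, labels, subject_id = subject_id))
      }
      a[ut] <- rpois(sum(ut), mu[ut])
      a[lower.tri(a)] <- 0
      a <- a + t(a)
    }
    abort("Could not generate a connected connectome within the retry budget.",
          class = "boldband_error_connectivity")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate band-limited BOLD with plantable band energies
#'
#' Draws spectral coefficients in the low and high bands of the supplied
#' basis (scales `sigma_low`, `sigma_high`), inverse-transforms to region
#' space, and — for any (region, band) rows named in `targets` — adjusts
#' the band component by alternating row-rescaling and band reprojection
#' until the measured band energies match the targets (to `1e-8` at zero
#' noise). The per-region energies of a K-mode band have only
#' `K (K + 1) / 2` degrees of freedom, so only a modest number of exact
#' targets per band is feasible; unconstrained regions keep their random
#' energies. The returned series carries the `"zscored"` stage tag: it is
#' analysis-ready by construction (planted directly in graph-spectral
#' space), and running the time-domain preprocessing on it would destroy
#' the planted energies.
#'
#' @param basis A `spectral_basis`.
#' @param targets Optional tibble `region`, `band` (`"low"`/`"high"`),
#'   `energy` of exact energy constraints.
#' @param n_timepoints Series length (analysis-ready frames).
#' @param k_band Modes per band.
#' @param sigma_low,sigma_high Spectral coefficient SD per band.
#' @param noise_sd Additive white-noise SD in region space.
#' @param tr Repetition time (seconds).
#' @param seed Optional integer seed.
#' @return A `bold_series` at stage `"zscored"`.
#' @export
gen_bold <- function(basis, targets = NULL, n_timepoints = 145, k_band = 10,
                     sigma_low = 1, sigma_high = 1, noise_sd = 0, tr = 2,
                     seed = NULL) {
  stopifnot(inherits(basis, "spectral_basis"))
  if (!is.null(targets) && any(targets$energy < 0)) {
    abort("Target energies must be nonnegative.",
          class = "boldband_error_target")
  }
  run <- function() {
    n <- length(basis$eigenvalues)
    sigmas <- c(low = sigma_low, high = sigma_high)
    vals <- matrix(0, n, n_timepoints,
                   dimnames = list(basis$region_labels, NULL))
    for (b in c("low", "high")) {
      filt <- make_band_filter(basis, b, k_band)
      vb <- basis$eigenvectors[, filt$mode_index, drop = FALSE]
      yb <- vb %*% matrix(rnorm(k_band * n_timepoints, sd = sigmas[[b]]),
                          k_band, n_timepoints)
      tgt <- if (is.null(targets)) NULL else
        targets[targets$band == b, , drop = FALSE]
      if (!is.null(tgt) && nrow(tgt)) {
        rows <- match(tgt$region, basis$region_labels)
        if (anyNA(rows)) {
          abort("Target region not found in the basis labels.",
                class = "boldband_error_target")
        }
        e_tgt <- tgt$energy
        ok <- FALSE
        for (iter in 1:2000) {
          rn <- sqrt(rowSums(yb[rows, , drop = FALSE]^2))
          if (max(abs(rn - e_tgt)) < 1e-10 * max(e_tgt, 1)) { ok <- TRUE; break }
          yb[rows, ] <- yb[rows, , drop = FALSE] *
            (e_tgt / pmax(rn, 1e-12))
          yb <- vb %*% crossprod(vb, yb)
        }
        if (!ok) {
          warn(sprintf(
            "Planted %s-band energies converged to %.2e of target only.",
            b, max(abs(sqrt(rowSums(yb[rows, , drop = FALSE]^2)) - e_tgt))),
            class = "boldband_warning_target")
        }
      }
      vals <- vals + yb
    }
    if (noise_sd > 0) {
      if (!is.null(targets) && any(targets$energy == 0)) {
        warn("Zero-energy target with nonzero noise cannot be met exactly.",
             class = "boldband_warning_target")
      }
      vals <- vals + matrix(rnorm(n * n_timepoints, sd = noise_sd),
                            n, n_timepoints)
    }
    bold_series(vals, tr = tr, region_labels = basis$region_labels,
                subject_id = basis$subject_id, stage = "zscored")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate subject outcomes from a feature table
#'
#' Ages are Normal(`age_mean`, `age_sd`^2) truncated below at `age_min`;
#' serum NfL is `beta0 + beta_age * age + sum_j beta_j * z(feature_j) +`
#' Gaussian noise, floored at 0.1 pg/mL, where `z()` standardizes the
#' measured feature across subjects so planted effects are in SD units.
#'
#' @param features_wide Wide feature tibble from [widen_features()].
#' @param config A `synth_config` (supplies the outcome model and the
#'   planted effects).
#' @param seed Optional integer seed.
#' @return Records tibble: `subject_id`, `cohort`, `age`, `serum_nfl`.
#' @export
gen_outcomes <- function(features_wide, config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  run <- function() {
    n <- nrow(features_wide)
    age <- rnorm(n, config$age_mean, config$age_sd)
    while (any(age < config$age_min)) {
      age[age < config$age_min] <- rnorm(sum(age < config$age_min),
                                         config$age_mean, config$age_sd)
    }
    nfl <- config$beta0 + config$beta_age * age
    if (nrow(config$planted)) {
      for (j in seq_len(nrow(config$planted))) {
        fname <- paste(config$planted$band[j], config$planted$region[j],
                       sep = "__")
        if (!fname %in% names(features_wide)) {
          abort(sprintf("Planted feature %s not found.", fname),
                class = "boldband_error_target")
        }
        nfl <- nfl + config$planted$beta[j] *
          drop(scale(features_wide[[fname]]))
      }
    }
    nfl <- pmax(nfl + rnorm(n, 0, config$nfl_sd), 0.1)
    tibble(subject_id = features_wide$subject_id, cohort = config$cohort,
           age = age, serum_nfl = nfl)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a full synthetic cohort
#'
#' Per subject: a modular connectome, its spectral basis, and an
#' analysis-ready BOLD series whose planted (region, band) energies are
#' drawn as Normal(`energy_mean`, `energy_sd`^2) (floored at 0.1) and hit
#' exactly; then outcomes from the linear NfL model. Fully deterministic
#' under the master seed.
#'
#' @param config A `synth_config`.
#' @param seed Master integer seed (required).
#' @return List: `subjects` (per-subject `connectome`/`bold`/`covariates`
#'   lists, the input shape of [build_feature_table()]), `features` (tidy),
#'   `features_wide`, `records`, `config`, `seed`.
#' @export
gen_cohort <- function(config = synth_config(), seed) {
  if (missing(seed)) abort("`seed` is required.", class = "boldband_error_seed")
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(seed, {
    t_ready <- config$n_timepoints - floor(18 / config$tr)
    subjects <- purrr::map(seq_len(config$n_subjects), function(s) {
      id <- sprintf("%s-%02d", config$cohort, s)
      con <- gen_connectome(config$n_regions, config$n_modules,
                            config$within_mean, config$between_mean,
                            subject_id = id)
      basis <- eigendecompose(con)
      targets <- NULL
      if (nrow(config$planted)) {
        targets <- tibble(
          region = config$planted$region,
          band = config$planted$band,
          energy = pmax(rnorm(nrow(config$planted), config$energy_mean,
                              config$energy_sd), 0.1)
        )
      }
      bold <- gen_bold(basis, targets = targets, n_timepoints = t_ready,
                       k_band = config$k_band,
                       sigma_low = config$sigma_low,
                       sigma_high = config$sigma_high,
                       noise_sd = config$bold_noise_sd, tr = config$tr)
      list(connectome = con, bold = bold,
           covariates = list(cohort = config$cohort))
    })
    features <- build_feature_table(subjects, K = config$k_band)
    features_wide <- widen_features(features)
    records <- gen_outcomes(features_wide, config)
    list(subjects = subjects, features = features,
         features_wide = features_wide, records = records,
         config = config, seed = seed)
  })
}

#' Generate two cohorts with independently planted features
#'
#' Supports cohort-specificity experiments: with disjoint planted feature
#' sets the cohorts emulate populations whose NfL models do not transfer.
#'
#' @param config_a,config_b `synth_config`s for the two cohorts.
#' @param seed Master integer seed.
#' @return List with elements `a` and `b`, each as [gen_cohort()].
#' @export
gen_two_cohorts <- function(config_a, config_b, seed) {
  if (missing(seed)) abort("`seed` is required.", class = "boldband_error_seed")
  list(a = gen_cohort(config_a, seed = seed),
       b = gen_cohort(config_b, seed = seed + 104729L))
}

#' Generate a mediation triplet with known path coefficients
#'
#' `X` is age-like Normal(`x_mean`, `x_sd`^2); the mediator is
#' `m0 + a X + noise`; the outcome is `y0 + c_prime X + b M + noise`, so the
#' generative paths are exactly (`a`, `b`, `c_prime`) with total effect
#' `c_prime + a b`.
#'
#' @param n Sample size.
#' @param a,b,c_prime Generative path coefficients.
#' @param x_mean,x_sd Predictor distribution.
#' @param m0,m_sd Mediator intercept and noise SD.
#' @param y0,y_sd Outcome intercept and noise SD.
#' @param seed Integer seed (required).
#' @return Tibble `x`, `m`, `y`.
#' @export
gen_mediation_data <- function(n, a = -0.05, b = -2.2, c_prime = 0.16,
                               x_mean = 50, x_sd = 11,
                               m0 = 5, m_sd = 0.3, y0 = 5, y_sd = 1, seed) {
  if (missing(seed)) abort("`seed` is required.", class = "boldband_error_seed")
  stopifnot(m_sd > 0, y_sd > 0)
  withr::with_seed(seed, {
    x <- rnorm(n, x_mean, x_sd)
    m <- m0 + a * x + rnorm(n, 0, m_sd)
    y <- y0 + c_prime * x + b * m + rnorm(n, 0, y_sd)
    tibble(x = x, m = m, y = y)
  })
}

#' Generate moderation data with a known interaction coefficient
#'
#' Volume-scale outcome from covariate (age), focal predictor `x` (a band
#' energy), moderator `w` (serum NfL), and their product with coefficient
#' `b_int`. Continuous predictors enter the generator centered, which
#' leaves the product coefficient — the recovery target — unchanged.
#'
#' @param n Sample size.
#' @param intercept,b_age,b_x,b_w,b_int Generative coefficients.
#' @param noise_sd Residual SD (outcome units, mm^3 at the defaults).
#' @param seed Integer seed (required).
#' @return Tibble `y`, `x`, `w`, `age`.
#' @export
gen_moderation_data <- function(n, intercept = 1679.6, b_age = -11.09,
                                b_x = 30.25, b_w = 8.09, b_int = 16.495,
                                noise_sd = 50, seed) {
  if (missing(seed)) abort("`seed` is required.", class = "boldband_error_seed")
  stopifnot(noise_sd > 0)
  withr::with_seed(seed, {
    age <- rnorm(n, 50, 11)
    w <- pmax(rnorm(n, 10, 3), 0.1)     # serum NfL, pg/mL
    x <- pmax(rnorm(n, 12, 2), 0.1)     # band energy, arbitrary units
    y <- intercept + b_age * (age - 50) + b_x * (x - 12) + b_w * (w - 10) +
      b_int * (x - 12) * (w - 10) + rnorm(n, 0, noise_sd)
    tibble(y = y, x = x, w = w, age = age)
  })
}
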