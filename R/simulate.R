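#' Configuration for the synthetic census generator
#'
#' Bundles the "truth" of a simulated enrichment-planting study: a cohort of
#' shade-tolerant tree seedlings planted under heterogeneous canopy, measured
#' at a fixed set of irregular census days, growing by the power-law model
#' \eqn{dM/dt = \alpha M^\beta} and dying by a constant within-interval
#' hazard on the complementary log-log scale. Defaults emulate a 15-species
#' dipterocarp planting followed for about nine years: seven censuses,
#' canopy openness 0.5--26%, initial basal diameters around 4.1 mm, species
#' growth coefficients spanning roughly 4.3e-4 to 9.1e-4 mm mm^-1 day^-1
#' with a common scaling exponent of 0.86, annual mortality between about
#' 0.05 and 0.18 at reference conditions, and a positive cross-species
#' coupling between growth and mortality carried by a latent wood-density
#' axis.
#'
#' @param n_species Number of species.
#' @param n_individuals Individuals per species (scalar or length
#'   `n_species`).
#' @param census_days Strictly increasing census days since planting.
#' @param true_beta Common scaling exponent, in (0, 1).
#' @param species_log_alpha_mean,species_log_alpha_sd Mean and SD of the
#'   species-level log growth coefficient (log mm mm^-1 day^-1), evaluated
#'   at 1% canopy openness (log openness 0).
#' @param light_slope_alpha Slope of log(alpha) per unit log canopy
#'   openness.
#' @param m0_mean,m0_sd Median initial diameter at planting (mm) and the
#'   log-scale SD of the between-individual planting-stock variation;
#'   initial sizes are lognormal (positive, right-skewed, as nursery
#'   diameter distributions are).
#' @param individual_re_sd Length-3 SDs of individual random effects on
#'   (log alpha, logit beta, log M0).
#' @param residual_sd_by_species Measurement-error SD in mm; scalar or one
#'   value per species.
#' @param mort_eta_mean,mort_eta_sd Mean and SD of species annual-mortality
#'   intercepts on the cloglog scale, parameterized at the reference
#'   covariates (`ref_light`, `ref_size`).
#' @param mort_light_slope Mortality cloglog slope per % canopy openness.
#' @param mort_size_slope Mortality cloglog slope per mm initial diameter.
#' @param mort_individual_re_sd,mort_census_re_sd SDs of the mortality
#'   random intercepts for individual and census occasion.
#' @param tradeoff_corr Cross-species correlation between log alpha and the
#'   mortality intercept, in [-1, 1].
#' @param wd_loading Loading of wood density on the species growth axis, in
#'   [-1, 1]; negative values give denser-wooded species slower growth and
#'   (through `tradeoff_corr`) lower mortality.
#' @param openness_range Canopy-openness range in percent; individuals draw
#'   a static openness log-uniformly from this range.
#' @param openness_jitter_sd Log-scale SD of optional per-census jitter
#'   around each individual's openness (0 = static readings).
#' @param ref_light,ref_size Reference canopy openness (%) and initial
#'   diameter (mm) at which mortality intercepts are defined.
#' @param height_allom Coefficients `c(a, b)` of the deterministic height
#'   allometry `height_cm = a * diameter_mm^b` used only to drive the
#'   160-cm canopy-averaging rule.
#' @param seed Integer RNG seed.
#' @return An object of class `growmort_sim_config` (a named list).
#' @seealso [simulate_population()], [simulate_traits()]
#' @export
sim_config <- function(n_species = 15,
                       n_individuals = 68,
                       census_days = c(576, 815, 1166, 1474, 2885, 3214, 3543),
                       true_beta = 0.86,
                       species_log_alpha_mean = log(6.23e-4),
                       species_log_alpha_sd = 0.19,
                       light_slope_alpha = 0.092,
                       m0_mean = 4.12,
                       m0_sd = 0.18,
                       individual_re_sd = c(log_alpha = 0.25, logit_beta = 0.2, log_m0 = 0.1),
                       residual_sd_by_species = NULL,
                       mort_eta_mean = -2.25,
                       mort_eta_sd = 0.32,
                       mort_light_slope = -0.11,
                       mort_size_slope = -0.01,
                       mort_individual_re_sd = 0.2,
                       mort_census_re_sd = 0.2,
                       tradeoff_corr = 0.6,
                       wd_loading = -0.74,
                       openness_range = c(0.5, 26),
                       openness_jitter_sd = 0,
                       ref_light = 4.5,
                       ref_size = 4.12,
                       height_allom = c(a = 8, b = 1.2),
                       seed = 1L) {
  if (is.null(residual_sd_by_species)) {
    residual_sd_by_species <- seq(0.2, 0.5, length.out = n_species)
  }
  cfg <- list(
    n_species = as.integer(n_species),
    n_individuals = rep_len(as.integer(n_individuals), n_species),
    census_days = as.numeric(census_days),
    true_beta = true_beta,
    species_log_alpha_mean = species_log_alpha_mean,
    species_log_alpha_sd = species_log_alpha_sd,
    light_slope_alpha = light_slope_alpha,
    m0_mean = m0_mean, m0_sd = m0_sd,
    individual_re_sd = rep_len(as.numeric(individual_re_sd), 3L),
    residual_sd_by_species = rep_len(as.numeric(residual_sd_by_species), n_species),
    mort_eta_mean = mort_eta_mean, mort_eta_sd = mort_eta_sd,
    mort_light_slope = mort_light_slope,
    mort_size_slope = mort_size_slope,
    mort_individual_re_sd = mort_individual_re_sd,
    mort_census_re_sd = mort_census_re_sd,
    tradeoff_corr = tradeoff_corr,
    wd_loading = wd_loading,
    openness_range = as.numeric(openness_range),
    openness_jitter_sd = openness_jitter_sd,
    ref_light = ref_light, ref_size = ref_size,
    height_allom = rep_len(as.numeric(height_allom), 2L),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "growmort_sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_species >= 1, all(cfg$n_individuals >= 1))
  if (any(diff(cfg$census_days) <= 0)) {
    stop("`census_days` must be strictly increasing", call. = FALSE)
  }
  if (!(cfg$true_beta > 0 && cfg$true_beta < 1)) {
    stop("`true_beta` must lie in (0, 1)", call. = FALSE)
  }
  sds <- c(cfg$species_log_alpha_sd, cfg$m0_sd, cfg$individual_re_sd,
           cfg$residual_sd_by_species, cfg$mort_eta_sd,
           cfg$mort_individual_re_sd, cfg$mort_census_re_sd,
           cfg$openness_jitter_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (abs(cfg$tradeoff_corr) > 1) {
    stop("`tradeoff_corr` must lie in [-1, 1]", call. = FALSE)
  }
  if (abs(cfg$wd_loading) > 1) {
    stop("`wd_loading` must lie in [-1, 1]", call. = FALSE)
  }
  rng <- cfg$openness_range
  if (!(rng[1] > 0 && rng[2] <= 100 && rng[1] <= rng[2])) {
    stop("`openness_range` must lie within (0, 100]", call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate a multi-census seedling population
#'
#' Draws a full synthetic study from a [sim_config()]: species growth and
#' mortality intercepts from a bivariate normal with correlation
#' `tradeoff_corr`, individual random effects on (log alpha, logit beta,
#' M0), a static (optionally jittered) canopy-openness reading per
#' individual, latent diameters from the analytic power-law trajectory, and
#' interval-censored deaths from a cloglog hazard scaled by interval length
#' in years. Observations after an individual's death census are truncated;
#' the diameter at the death census is recorded as missing (a dead stem is
#' not measured).
#'
#' The logit-scale random effect on beta keeps every individual exponent in
#' (0, 1), i.e. on the sub-exponential branch of the growth model.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list of class `growmort_sim` with elements
#'   `census` (tibble: `individual_id`, `species_id`, `census_day`,
#'   `diameter_mm`, `height_cm`, `canopy_openness_pct`, `alive`),
#'   `traits` (see [simulate_traits()]), and `truth` (species- and
#'   individual-level latent parameters plus the config).
#' @examples
#' sim <- simulate_population(sim_config(n_species = 3, n_individuals = 5))
#' head(sim$census)
#' @export
simulate_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "growmort_sim_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  withr::with_seed(seed, {
    truth <- draw_truth(config)
    census <- draw_census(config, truth)
    traits <- draw_traits(config, truth)
  })
  structure(list(census = census, traits = traits, truth = truth),
            class = "growmort_sim")
}

draw_truth <- function(cfg) {
  ns <- cfg$n_species
  rho <- cfg$tradeoff_corr
  z_g <- stats::rnorm(ns)
  z_m <- rho * z_g + sqrt(1 - rho^2) * stats::rnorm(ns)
  species <- tibble::tibble(
    species_id = sprintf("sp%02d", seq_len(ns)),
    log_alpha = cfg$species_log_alpha_mean + cfg$species_log_alpha_sd * z_g,
    alpha = exp(.data$log_alpha),
    mort_eta_ref = cfg$mort_eta_mean + cfg$mort_eta_sd * z_m,
    annual_mortality_ref = cloglog_prob(.data$mort_eta_ref, delta_t = 1),
    resid_sd = cfg$residual_sd_by_species,
    z_growth = z_g, z_mort = z_m
  )
  if (any(!is.finite(species$log_alpha)) || any(!is.finite(species$mort_eta_ref))) {
    stop("non-finite species parameter draws; check sim_config means/SDs",
         call. = FALSE)
  }

  individuals <- purrr::map2_dfr(
    seq_len(ns), cfg$n_individuals,
    function(s, n_ind) {
      open <- exp(stats::runif(n_ind, log(cfg$openness_range[1]),
                               log(cfg$openness_range[2])))
      m0 <- exp(stats::rnorm(n_ind, log(cfg$m0_mean),
                             sqrt(cfg$m0_sd^2 + cfg$individual_re_sd[3]^2)))
      tibble::tibble(
        individual_id = sprintf("sp%02d_i%03d", s, seq_len(n_ind)),
        species_id = sprintf("sp%02d", s),
        openness_pct = open,
        m0 = m0,
        log_alpha_i = species$log_alpha[s] +
          cfg$light_slope_alpha * log(open) +
          stats::rnorm(n_ind, 0, cfg$individual_re_sd[1]),
        beta_i = stats::plogis(stats::qlogis(cfg$true_beta) +
                                 stats::rnorm(n_ind, 0, cfg$individual_re_sd[2])),
        mort_re_i = stats::rnorm(n_ind, 0, cfg$mort_individual_re_sd)
      )
    }
  )
  if (any(!is.finite(individuals$log_alpha_i))) {
    stop("non-finite individual parameter draws; check sim_config", call. = FALSE)
  }
  census_re <- stats::rnorm(length(cfg$census_days), 0, cfg$mort_census_re_sd)
  list(species = species, individuals = individuals,
       census_re = census_re, config = cfg)
}

draw_census <- function(cfg, truth) {
  days <- cfg$census_days
  k <- length(days)
  ind <- truth$individuals
  n <- nrow(ind)
  resid_sd <- truth$species$resid_sd[match(ind$species_id, truth$species$species_id)]

  # latent trajectory per individual at every census day (n x k)
  latent <- vapply(seq_len(k), function(j) {
    predict_size(ind$m0, exp(ind$log_alpha_i), ind$beta_i, days[j])
  }, numeric(n))

  # interval-censored death: constant hazard within each census interval
  dt_years <- diff(c(days[1], days))[-1] / DAYS_PER_YEAR  # k-1 intervals
  death_interval <- rep(NA_integer_, n)
  alive <- matrix(1L, n, k)
  for (j in seq_len(k - 1)) {
    eta <- truth$species$mort_eta_ref[match(ind$species_id, truth$species$species_id)] +
      cfg$mort_light_slope * (ind$openness_pct - cfg$ref_light) +
      cfg$mort_size_slope * (ind$m0 - cfg$ref_size) +
      ind$mort_re_i + truth$census_re[j + 1]
    p <- cloglog_prob(eta, dt_years[j])
    at_risk <- is.na(death_interval)
    dies <- at_risk & (stats::runif(n) < p)
    death_interval[dies] <- j
    alive[death_interval %in% seq_len(j), (j + 1):k] <- 0L
  }
  truth$individuals$death_interval <- death_interval

  obs <- tidyr::expand_grid(row = seq_len(n), j = seq_len(k)) |>
    dplyr::mutate(
      individual_id = ind$individual_id[.data$row],
      species_id = ind$species_id[.data$row],
      census_day = days[.data$j],
      alive = alive[cbind(.data$row, .data$j)],
      latent = latent[cbind(.data$row, .data$j)]
    ) |>
    # drop censuses after the death census
    dplyr::filter(is.na(death_interval[.data$row]) | .data$j <= death_interval[.data$row] + 1L)

  openness <- ind$openness_pct[obs$row]
  if (cfg$openness_jitter_sd > 0) {
    openness <- pmin(openness * exp(stats::rnorm(length(openness), 0,
                                                 cfg$openness_jitter_sd)), 100)
  }
  obs |>
    dplyr::mutate(
      diameter_mm = dplyr::if_else(
        .data$alive == 1L,
        pmax(.data$latent + stats::rnorm(dplyr::n(), 0, resid_sd[.data$row]), 0.1),
        NA_real_
      ),
      height_cm = cfg$height_allom[1] * .data$latent^cfg$height_allom[2],
      canopy_openness_pct = openness
    ) |>
    dplyr::select("individual_id", "species_id", "census_day", "diameter_mm",
                  "height_cm", "canopy_openness_pct", "alive") |>
    dplyr::arrange(.data$individual_id, .data$census_day)
}

#' Simulate species traits linked to demography
#'
#' Generates a species trait table (wood density, SLA, seed mass, leaf C:N)
#' plus raw per-plant trait observations spread over several experiments for
#' the trait-mean estimator. Wood density loads (with `wd_loading`) on the
#' standardized species growth axis, so it correlates negatively with both
#' growth and -- through the growth--mortality coupling -- mortality; the
#' other three traits are drawn independently of demography.
#'
#' @param config A [sim_config()].
#' @param truth The `truth` element of a [simulate_population()] result.
#' @param n_experiments,n_plants_per Number of trait experiments and plants
#'   measured per species per experiment.
#' @param wd_noise_sd Residual SD of the standardized wood-density axis;
#'   with `wd_loading = -1` and `wd_noise_sd = 0` wood density is an exact
#'   linear map of the growth axis.
#' @return A list with `species` (one summary row per species, including the
#'   realized trait--demography correlations as attributes) and
#'   `observations` (long tibble: `species_id`, `experiment`, `trait`,
#'   `value`).
#' @export
simulate_traits <- function(config, truth, n_experiments = 3, n_plants_per = 8,
                            wd_noise_sd = NULL) {
  stopifnot(inherits(config, "growmort_sim_config"))
  if (abs(config$wd_loading) > 1) stop("`wd_loading` must lie in [-1, 1]", call. = FALSE)
  draw_traits(config, truth, n_experiments, n_plants_per, wd_noise_sd)
}

draw_traits <- function(cfg, truth, n_experiments = 3, n_plants_per = 8,
                        wd_noise_sd = NULL) {
  sp <- truth$species
  ns <- nrow(sp)
  l <- cfg$wd_loading
  if (is.null(wd_noise_sd)) wd_noise_sd <- sqrt(1 - l^2)
  z_growth_std <- if (ns > 1 && stats::sd(sp$log_alpha) > 0) {
    as.numeric(scale(sp$log_alpha))
  } else {
    rep(0, ns)
  }
  wd_z <- l * z_growth_std + wd_noise_sd * stats::rnorm(ns)
  species <- tibble::tibble(
    species_id = sp$species_id,
    wood_density = 0.55 + 0.08 * wd_z,             # g cm^-3
    sla = exp(stats::rnorm(ns, log(180), 0.20)),   # cm^2 g^-1
    seed_mass = exp(stats::rnorm(ns, log(1.5), 0.6)),  # g
    leaf_cn = stats::rnorm(ns, 35, 6)              # ratio
  )
  safe_cor <- function(a, b) {
    if (length(a) > 2 && stats::sd(a) > 0 && stats::sd(b) > 0) stats::cor(a, b) else NA_real_
  }
  realized <- c(
    wd_log_alpha = safe_cor(species$wood_density, sp$log_alpha),
    wd_mort_eta = safe_cor(species$wood_density, sp$mort_eta_ref)
  )
  attr(species, "realized_correlations") <- realized

  traits_long <- species |>
    tidyr::pivot_longer(-"species_id", names_to = "trait", values_to = "true_mean")
  exp_offsets <- tidyr::expand_grid(
    trait = unique(traits_long$trait),
    experiment = sprintf("exp%d", seq_len(n_experiments))
  ) |>
    dplyr::mutate(offset = stats::rnorm(dplyr::n(), 0, 0.1))
  observations <- traits_long |>
    tidyr::expand_grid(experiment = sprintf("exp%d", seq_len(n_experiments)),
                       rep = seq_len(n_plants_per)) |>
    dplyr::left_join(exp_offsets, by = c("trait", "experiment")) |>
    dplyr::mutate(
      value = .data$true_mean * (1 + .data$offset) +
        stats::rnorm(dplyr::n(), 0, 0.05 * abs(.data$true_mean))
    ) |>
    dplyr::select("species_id", "experiment", "trait", "value")
  list(species = species, observations = observations)
}
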