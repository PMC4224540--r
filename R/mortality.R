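#' Complementary log-log interval mortality probability
#'
#' Probability of dying within an observation interval of length `delta_t`
#' years under a constant hazard with linear predictor `eta` on the cloglog
#' scale: \eqn{p = 1 - \exp(-e^{\eta + \log \Delta t})}. The log-time offset
#' makes probabilities coherent across unequal census gaps (surviving two
#' back-to-back intervals equals surviving their union), and scales `eta` in
#' annual units.
#'
#' @param eta Linear predictor on the cloglog scale (annual).
#' @param delta_t Interval length in years, positive.
#' @return Death probability in [0, 1].
#' @seealso [cloglog_eta()] for the inverse.
#' @examples
#' cloglog_prob(cloglog_eta(0.1), delta_t = 2)  # 1 - 0.9^2
#' @export
cloglog_prob <- function(eta, delta_t = 1) {
  if (any(delta_t <= 0)) stop("`delta_t` must be positive", call. = FALSE)
  -expm1(-exp(pmin(eta + log(delta_t), 700)))
}

#' @rdname cloglog_prob
#' @param p Probability of death over `delta_t` years, in (0, 1).
#' @return For `cloglog_eta`, the annualized cloglog linear predictor
#'   \eqn{\log(-\log(1 - p)) - \log \Delta t}.
#' @export
cloglog_eta <- function(p, delta_t = 1) {
  if (any(p <= 0 | p >= 1)) stop("`p` must lie in (0, 1)", call. = FALSE)
  log(-log1p(-p)) - log(delta_t)
}

#' Build interval-censored mortality records from a census table
#'
#' Converts a longitudinal census table into one record per individual per
#' consecutive census pair at whose start the individual was alive. The
#' record is marked `died = 1` when the individual was dead at the interval
#' end; `delta_t` is the day gap divided by 365. The light covariate is, by
#' default, the individual's averaged canopy openness from
#' [average_canopy()] (per-census readings via `light = "per_census"`, in
#' which case the reading at the interval start is used); the size covariate
#' is the first recorded diameter of the individual.
#'
#' @param census A census tibble as produced by [simulate_population()].
#' @param light `"averaged"` (default) or `"per_census"`.
#' @param threshold_cm Height threshold for the canopy-averaging rule.
#' @return A tibble with columns `individual_id`, `species_id`,
#'   `interval_start`, `interval_end`, `delta_t` (years), `died`,
#'   `canopy_openness_pct`, `initial_diameter_mm`, `census_index` (index of
#'   the census closing the interval). Individuals with a single census
#'   contribute no rows.
#' @export
build_intervals <- function(census, light = c("averaged", "per_census"),
                            threshold_cm = 160) {
  light <- match.arg(light)
  check_census(census)
  avg <- average_canopy(census, threshold_cm = threshold_cm)
  census |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::arrange(.data$census_day, .by_group = TRUE) |>
    dplyr::mutate(
      census_index = dplyr::row_number(),
      initial_diameter_mm = dplyr::first(stats::na.omit(.data$diameter_mm))
    ) |>
    dplyr::mutate(
      interval_start = dplyr::lag(.data$census_day),
      alive_start = dplyr::lag(.data$alive),
      light_start = dplyr::lag(.data$canopy_openness_pct)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$interval_start), .data$alive_start == 1L) |>
    dplyr::left_join(avg, by = "individual_id") |>
    dplyr::transmute(
      .data$individual_id, .data$species_id,
      .data$interval_start, interval_end = .data$census_day,
      delta_t = (.data$census_day - .data$interval_start) / DAYS_PER_YEAR,
      died = 1L - .data$alive,
      canopy_openness_pct = if (light == "averaged") .data$mean_openness_pct else .data$light_start,
      .data$initial_diameter_mm,
      census_index = .data$census_index
    )
}

check_census <- function(census) {
  required <- c("individual_id", "species_id", "census_day", "diameter_mm",
                "canopy_openness_pct", "alive")
  missing_cols <- setdiff(required, names(census))
  if (length(missing_cols) > 0) {
    stop("census table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  resurrect <- census |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::arrange(.data$census_day, .by_group = TRUE) |>
    dplyr::summarise(bad = any(diff(.data$alive) > 0), .groups = "drop")
  if (any(resurrect$bad)) {
    stop("census table records an individual alive after being dead: ",
         paste(resurrect$individual_id[resurrect$bad], collapse = ", "),
         call. = FALSE)
  }
  invisible(census)
}

#' Fit the interval-censored cloglog mortality GLMM
#'
#' Binomial GLMM with complementary log-log link on interval death records:
#' fixed effects for species, canopy openness (%) and initial diameter (mm),
#' an offset of log interval length in years, and random intercepts for
#' individual and census occasion. Estimated by Laplace-approximated maximum
#' likelihood via [lme4::glmer()]. The offset annualizes the intercepts, so
#' back-transformed predictions are annual probabilities.
#'
#' @param intervals Interval records from [build_intervals()].
#' @param include_interaction Include a species-by-openness interaction
#'   (used for the BIC comparison mirroring the no-interaction selection).
#' @param log_light Use log canopy openness instead of the untransformed
#'   percentage (sensitivity option; default untransformed).
#' @param random_effects Which random intercepts to include.
#' @return An object of class `growmort_mortality_fit`: a list with the
#'   fitted `model`, tibbles of species intercepts and slopes, random-effect
#'   variances, `loglik`, `bic`, `n_obs`, `n_params` and a convergence flag.
#'   Species with no observed deaths push their intercept to the boundary;
#'   a warning lists them.
#' @export
fit_mortality <- function(intervals, include_interaction = FALSE,
                          log_light = FALSE,
                          random_effects = c("both", "individual", "census", "none")) {
  random_effects <- match.arg(random_effects)
  stopifnot(all(c("died", "delta_t", "species_id", "canopy_openness_pct",
                  "initial_diameter_mm", "census_index") %in% names(intervals)))
  if (sum(intervals$died) == 0) stop("no deaths in `intervals`; cannot fit", call. = FALSE)

  deaths_by_sp <- intervals |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(deaths = sum(.data$died), .groups = "drop")
  zero_death <- deaths_by_sp$species_id[deaths_by_sp$deaths == 0]
  if (length(zero_death) > 0) {
    warning("species with zero deaths (intercept at likelihood boundary): ",
            paste(zero_death, collapse = ", "), call. = FALSE)
  }

  dat <- intervals |>
    dplyr::mutate(
      species_id = factor(.data$species_id),
      light = if (log_light) log(.data$canopy_openness_pct) else .data$canopy_openness_pct,
      census_f = factor(.data$census_index),
      log_dt = log(.data$delta_t)
    )
  single_species <- nlevels(dat$species_id) < 2
  fe <- if (single_species) {
    "light"  # intercept plays the species role; renamed on extraction
  } else if (include_interaction) {
    "species_id * light"
  } else {
    "species_id + light"
  }
  re <- switch(random_effects,
    both = "+ (1 | individual_id) + (1 | census_f)",
    individual = "+ (1 | individual_id)",
    census = "+ (1 | census_f)",
    none = ""
  )
  lead <- if (single_species) "died ~" else "died ~ 0 +"
  form <- stats::as.formula(paste(
    lead, fe, "+ initial_diameter_mm", re, "+ offset(log_dt)"
  ))
  if (single_species && include_interaction) {
    stop("species-by-light interaction needs >= 2 species", call. = FALSE)
  }

  if (random_effects == "none") {
    model <- stats::glm(form, family = stats::binomial("cloglog"), data = dat)
    converged <- model$converged
    re_var <- c(individual = 0, census = 0)
  } else {
    model <- lme4::glmer(form, family = stats::binomial("cloglog"), data = dat,
                         control = lme4::glmerControl(calc.derivs = FALSE))
    converged <- length(model@optinfo$conv$lme4) == 0
    vc <- lme4::VarCorr(model)
    re_var <- c(
      individual = if ("individual_id" %in% names(vc)) as.numeric(vc$individual_id) else 0,
      census = if ("census_f" %in% names(vc)) as.numeric(vc$census_f) else 0
    )
  }

  fe_est <- if (inherits(model, "merMod")) lme4::fixef(model) else stats::coef(model)
  if (single_species) {
    names(fe_est)[names(fe_est) == "(Intercept)"] <-
      paste0("species_id", levels(dat$species_id))
    names(fe_est)[names(fe_est) == "canopy_openness_pct"] <- "light"
  }
  ll <- as.numeric(stats::logLik(model))
  structure(list(
    model = model,
    coefficients = tibble::tibble(term = names(fe_est), estimate = unname(fe_est)),
    re_var = re_var,
    species_levels = levels(dat$species_id),
    include_interaction = include_interaction,
    log_light = log_light,
    loglik = ll,
    n_obs = nrow(dat),
    n_params = attr(stats::logLik(model), "df"),
    bic = -2 * ll + attr(stats::logLik(model), "df") * log(nrow(dat)),
    deaths = sum(dat$died),
    converged = converged,
    zero_death_species = zero_death
  ), class = "growmort_mortality_fit")
}

#' Population-level annual mortality probability
#'
#' Inverts the fitted cloglog model at `delta_t` = 1 year with random
#' effects at zero: the annual death probability for a given species, canopy
#' openness and initial diameter.
#'
#' @param fit A `growmort_mortality_fit`.
#' @param species Character vector of species ids (default: all in the fit).
#' @param light Canopy openness in % (recycled).
#' @param size Initial diameter in mm (recycled).
#' @return Tibble with `species_id`, `light`, `size`, `eta`,
#'   `annual_mortality`.
#' @export
annual_mortality <- function(fit, species = NULL, light = 4.5, size = 4.12) {
  stopifnot(inherits(fit, "growmort_mortality_fit"))
  if (is.null(species)) species <- fit$species_levels
  unseen <- setdiff(species, fit$species_levels)
  if (length(unseen) > 0) {
    stop("species not in the fitted model: ", paste(unseen, collapse = ", "),
         call. = FALSE)
  }
  grid <- tibble::tibble(species_id = species) |>
    tidyr::expand_grid(tibble::tibble(light = light, size = size))
  co <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  lt <- if (fit$log_light) log(grid$light) else grid$light
  eta <- co[paste0("species_id", grid$species_id)] +
    co["light"] * lt +
    co["initial_diameter_mm"] * grid$size
  if (fit$include_interaction) {
    inter <- paste0("species_id", grid$species_id, ":light")
    eta <- eta + ifelse(inter %in% names(co), co[inter], 0) * lt
  }
  grid |>
    dplyr::mutate(eta = unname(eta),
                  annual_mortality = cloglog_prob(.data$eta, delta_t = 1))
}
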