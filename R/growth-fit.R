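# Nonlinear mixed-effects estimator for the power-law growth model.
#
# Internal parameterization (one value per individual i):
#   log alpha_i = lalpha_{species} + light_slope * log(openness_i) + b1_i
#   beta_i      = plogis(tbeta + b2_i)          # keeps beta on the (0,1) branch
#   M0_i        = exp(lm0 + b3_i)               # keeps initial size positive
# with (b1, b2, b3) independent individual-level Gaussian random effects and
# species-specific residual SDs (varIdent). Estimated with nlme's
# Lindstrom-Bates algorithm, staged: a one-dimensional random effect on
# log alpha seeds the full three-dimensional heteroscedastic model.

#' Power-law trajectory on the sampling scale, with analytic gradient
#'
#' The model function handed to the nonlinear mixed-effects engine:
#' evaluates the analytic power-law trajectory at `day` for parameters on
#' the unconstrained sampling scale — `lalpha` = log alpha, `tbeta` =
#' logit beta, `lm0` = log M0 — and attaches the symbolic gradient with
#' respect to all three (generated by [stats::deriv()]). Exported because
#' the fitting engine resolves the model function by name; users normally
#' call [fit_growth()] and [predict_size()] instead.
#'
#' @param day Days since planting.
#' @param lalpha,tbeta,lm0 Parameters on the sampling scale.
#' @return Predicted diameters (mm) with a `"gradient"` attribute.
#' @keywords internal
#' @export
growth_model <- stats::deriv(
  ~ ((exp(lm0))^(1 - (1 / (1 + exp(-tbeta)))) +
       exp(lalpha) * (1 - (1 / (1 + exp(-tbeta)))) * day)^
    (1 / (1 - (1 / (1 + exp(-tbeta))))),
  c("lalpha", "tbeta", "lm0"),
  function(day, lalpha, tbeta, lm0) {}
)

#' Prepare census data for growth fitting
#'
#' Filters to live, measured records, attaches the averaged canopy-openness
#' covariate ([average_canopy()]) and drops individuals with fewer than
#' `min_measures` diameter measures (they are retained for mortality
#' analysis, not for growth).
#'
#' @inheritParams average_canopy
#' @param min_measures Minimum diameter measures per individual (default 3).
#' @return Tibble with `log_open` and a `species_id` factor; the number of
#'   excluded individuals is attached as attribute `n_excluded`.
#' @export
prepare_growth_data <- function(census, min_measures = 3, threshold_cm = 160) {
  check_census(census)
  avg <- average_canopy(census, threshold_cm = threshold_cm)
  measured <- census |>
    dplyr::filter(.data$alive == 1L, !is.na(.data$diameter_mm)) |>
    dplyr::left_join(avg, by = "individual_id")
  keep <- measured |>
    dplyr::count(.data$individual_id) |>
    dplyr::filter(.data$n >= min_measures)
  n_excluded <- dplyr::n_distinct(measured$individual_id) - nrow(keep)
  if (n_excluded > 0) {
    message(n_excluded, " individual(s) with < ", min_measures,
            " measures excluded from growth fitting")
  }
  out <- measured |>
    dplyr::semi_join(keep, by = "individual_id") |>
    dplyr::mutate(log_open = log(.data$mean_openness_pct),
                  species_id = factor(.data$species_id))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Fit the power-law growth model by nonlinear mixed effects
#'
#' Fits the analytic power-law trajectory (see [predict_size()]) to repeated
#' diameter measures with species intercepts and a log canopy-openness slope
#' on log alpha, a common scaling exponent beta and common initial size M0,
#' individual random effects on all three parameters, and (optionally) a
#' separate residual variance per species. Estimation uses
#' [nlme::nlme()]; `method = "ML"` for BIC model comparison, `"REML"` for
#' reported estimates.
#'
#' @param census A census table (see [simulate_population()]).
#' @param method `"REML"` (reported estimates) or `"ML"` (model comparison).
#' @param species_light_interaction Allow the log-openness slope to differ
#'   by species (the interaction model used in BIC comparisons).
#' @param per_species_variance Use a separate residual SD per species
#'   (`nlme::varIdent`); `FALSE` gives a single common SD.
#' @param min_measures,threshold_cm Passed to [prepare_growth_data()].
#' @param control An [nlme::nlmeControl()] list.
#' @return An object of class `growmort_growth_fit`; see [tidy.growmort_growth_fit()]
#'   and [glance.growmort_growth_fit()]. Key elements: `params` (named list
#'   with `alpha_by_species` tibble, `light_slope`, `beta`, `m0`, `re_sd`,
#'   `resid_sd_by_species`), `loglik`, `bic`, `pseudo_r2`, `vcov_fixed`,
#'   `converged`, and the underlying `model`.
#' @examples
#' \donttest{
#' sim <- simulate_population(sim_config(n_species = 4, n_individuals = 15))
#' fit <- fit_growth(sim$census, method = "ML")
#' glance(fit)
#' }
#' @export
fit_growth <- function(census,
                       method = c("REML", "ML"),
                       species_light_interaction = FALSE,
                       per_species_variance = TRUE,
                       min_measures = 3,
                       threshold_cm = 160,
                       control = NULL) {
  method <- match.arg(method)
  dat <- prepare_growth_data(census, min_measures = min_measures,
                             threshold_cm = threshold_cm)
  if (nrow(dat) == 0) stop("no usable growth observations", call. = FALSE)
  if (is.null(control)) {
    control <- nlme::nlmeControl(maxIter = 100, msMaxIter = 200,
                                 pnlsMaxIter = 10, niterEM = 30)
  }
  ns <- nlevels(dat$species_id)

  # starting values: per-individual log-linear slope of log diameter on time
  # seeds the species log-alpha intercepts; beta starts at 0.8; M0 at the
  # mean first-census diameter.
  ind_slopes <- dat |>
    dplyr::group_by(.data$species_id, .data$individual_id) |>
    dplyr::summarise(
      slope = stats::coef(stats::lm(log(diameter_mm) ~ census_day,
                                    data = dplyr::pick(dplyr::everything())))[2],
      .groups = "drop"
    )
  sp_start <- ind_slopes |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(lalpha = log(pmax(stats::median(.data$slope, na.rm = TRUE), 1e-5)),
                     .groups = "drop")
  m0_start <- dat |>
    dplyr::filter(.data$census_day == min(.data$census_day)) |>
    dplyr::pull(.data$diameter_mm) |>
    mean()
  start_fixed <- c(sp_start$lalpha, 0, stats::qlogis(0.8), log(m0_start))

  fixed_formula <- if (species_light_interaction) {
    list(lalpha ~ 0 + species_id + species_id:log_open, tbeta ~ 1, lm0 ~ 1)
  } else {
    list(lalpha ~ 0 + species_id + log_open, tbeta ~ 1, lm0 ~ 1)
  }
  if (species_light_interaction) {
    start_fixed <- c(sp_start$lalpha, rep(0, ns), stats::qlogis(0.8), log(m0_start))
  }

  base_args <- list(
    model = diameter_mm ~ growmort::growth_model(census_day, lalpha, tbeta, lm0),
    data = dat,
    fixed = fixed_formula,
    groups = ~individual_id,
    method = method,
    control = control
  )
  # a failed PNLS step at one starting point is retried from alternative
  # beta starts before giving up
  stage1 <- NULL
  tb_idx <- length(start_fixed) - 1L
  for (tb_start in stats::qlogis(c(0.8, 0.6, 0.9, 0.95))) {
    start_try <- start_fixed
    start_try[tb_idx] <- tb_start
    stage1 <- tryCatch(
      do.call(nlme::nlme, c(base_args, list(random = lalpha ~ 1, start = start_try))),
      error = function(e) e
    )
    if (!inherits(stage1, "error")) break
  }
  if (inherits(stage1, "error")) {
    stop("growth NLME failed to converge from any starting point: ",
         conditionMessage(stage1), call. = FALSE)
  }

  weights <- if (per_species_variance) nlme::varIdent(form = ~1 | species_id)
  refit <- function(random) {
    args <- c(base_args, list(random = random, start = nlme::fixef(stage1)))
    if (!is.null(weights)) args$weights <- weights
    tryCatch(do.call(nlme::nlme, args), error = function(e) e)
  }
  # full three-dimensional random effects; progressively simpler structures
  # are tried when the Lindstrom-Bates iterations fail outright
  converged <- TRUE
  convergence_note <- NA_character_
  model <- refit(nlme::pdDiag(lalpha + tbeta + lm0 ~ 1))
  if (inherits(model, "error")) {
    convergence_note <- conditionMessage(model)
    converged <- FALSE
    model <- refit(nlme::pdDiag(lalpha + lm0 ~ 1))
    if (inherits(model, "error")) model <- refit(lalpha ~ 1)
    if (inherits(model, "error")) model <- stage1
  }

  build_growth_fit(model, dat, method = method,
                   species_light_interaction = species_light_interaction,
                   per_species_variance = per_species_variance,
                   converged = converged, convergence_note = convergence_note)
}

build_growth_fit <- function(model, dat, method, species_light_interaction,
                             per_species_variance, converged, convergence_note) {
  fe <- nlme::fixef(model)
  ns <- nlevels(dat$species_id)
  sp_levels <- levels(dat$species_id)
  sp_idx <- paste0("lalpha.species_id", sp_levels)
  alpha_tbl <- tibble::tibble(
    species_id = sp_levels,
    log_alpha = unname(fe[sp_idx]),
    alpha = exp(.data$log_alpha)
  )
  light_slope <- if (species_light_interaction) {
    unname(fe[grepl("log_open", names(fe))])
  } else {
    unname(fe[["lalpha.log_open"]])
  }
  tbeta <- unname(fe[["tbeta"]])
  se_tbeta <- sqrt(diag(stats::vcov(model))[["tbeta"]])
  re_sd <- tryCatch({
    vc <- nlme::VarCorr(model)
    sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
    nm <- rownames(vc)
    keep <- nm != "Residual" & !is.na(sds)
    stats::setNames(
      sds[keep],
      c(lalpha = "log_alpha", `lalpha.(Intercept)` = "log_alpha",
        tbeta = "logit_beta", lm0 = "log_m0")[nm[keep]]
    )
  }, error = function(e) NULL)
  sigma <- model$sigma
  var_struct <- model$modelStruct$varStruct
  resid_sd <- if (!is.null(var_struct)) {
    mult <- stats::coef(var_struct, unconstrained = FALSE, allCoef = TRUE)
    grp <- attr(var_struct, "groupNames")
    stats::setNames(sigma * unname(mult)[match(sp_levels, grp)], sp_levels)
  } else {
    stats::setNames(rep(sigma, ns), sp_levels)
  }
  ll <- stats::logLik(model)
  n_obs <- nrow(dat)
  fitted_cond <- as.numeric(stats::fitted(model, level = 1))
  fitted_marg <- as.numeric(stats::fitted(model, level = 0))
  pr2 <- function(f) {
    if (stats::sd(f) == 0 || anyNA(f)) return(NA_real_)
    stats::cor(f, dat$diameter_mm)^2
  }
  structure(list(
    model = model,
    data = dat,
    method = method,
    species_light_interaction = species_light_interaction,
    per_species_variance = per_species_variance,
    params = list(
      alpha_by_species = alpha_tbl,
      light_slope = light_slope,
      beta = stats::plogis(tbeta),
      beta_ci = stats::plogis(tbeta + c(-1, 1) * stats::qnorm(0.975) * se_tbeta),
      tbeta = tbeta,
      m0 = exp(unname(fe[["lm0"]])),
      re_sd = re_sd,
      resid_sd_by_species = resid_sd,
      sigma = sigma
    ),
    fixed_effects = fe,
    vcov_fixed = as.matrix(stats::vcov(model)),
    fitted_conditional = fitted_cond,
    fitted_marginal = fitted_marg,
    loglik = as.numeric(ll),
    n_params = attr(ll, "df"),
    n_obs = n_obs,
    n_individuals = dplyr::n_distinct(dat$individual_id),
    bic = -2 * as.numeric(ll) + attr(ll, "df") * log(n_obs),
    pseudo_r2 = pr2(fitted_cond),
    pseudo_r2_marginal = pr2(fitted_marg),
    converged = converged,
    convergence_note = convergence_note
  ), class = "growmort_growth_fit")
}

#' Squared fitted-observed correlation of a growth fit
#'
#' Mixed models report no conventional R-squared; this pseudo-R2 is the
#' squared Pearson correlation between fitted and observed diameters.
#' Conditional fitted values (including the individual random effects) are
#' the default; marginal (population-level) values are available for
#' comparison.
#'
#' @param fit A `growmort_growth_fit`.
#' @param level `"conditional"` or `"marginal"`.
#' @return A single number in [0, 1].
#' @export
pseudo_r2 <- function(fit, level = c("conditional", "marginal")) {
  stopifnot(inherits(fit, "growmort_growth_fit"))
  level <- match.arg(level)
  out <- if (level == "conditional") fit$pseudo_r2 else fit$pseudo_r2_marginal
  if (is.na(out)) stop("pseudo-R2 undefined (constant or missing fitted values)",
                       call. = FALSE)
  out
}

#' Rank models by BIC with a two-point preference rule
#'
#' Compares maximum-likelihood fits of the same data by Schwarz's BIC. A
#' model is preferred when its BIC is more than two points below the rest;
#' models within two points are treated as indistinguishable and the one
#' with the fewest parameters is retained.
#'
#' @param ... Named `growmort_growth_fit` or `growmort_mortality_fit`
#'   objects (or a single list of them), all fitted to the same data with
#'   ML.
#' @return A tibble sorted by BIC with `model`, `n_params`, `loglik`, `bic`,
#'   `delta_bic`, `preferred`; the retained model name is attached as
#'   attribute `preferred`.
#' @export
compare_bic <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], c("growmort_growth_fit", "growmort_mortality_fit"))) {
    fits <- fits[[1]]
  }
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  n_obs <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n_obs)) != 1) {
    stop("fits use different data (observation counts differ); BIC not comparable",
         call. = FALSE)
  }
  reml <- vapply(fits, function(f) identical(f$method, "REML"), logical(1))
  if (any(reml)) {
    warning("BIC comparison expects ML fits; REML fits supplied: ",
            paste(names(fits)[reml], collapse = ", "), call. = FALSE)
  }
  tbl <- tibble::tibble(
    model = names(fits),
    n_params = vapply(fits, function(f) f$n_params, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1))
  ) |>
    dplyr::mutate(delta_bic = .data$bic - min(.data$bic)) |>
    dplyr::arrange(.data$bic)
  contenders <- tbl |> dplyr::filter(.data$delta_bic <= 2)
  preferred <- contenders$model[which.min(contenders$n_params)]
  tbl <- tbl |> dplyr::mutate(preferred = .data$model == preferred)
  attr(tbl, "preferred") <- preferred
  tbl
}

#' Parametric confidence band for a fitted growth trajectory
#'
#' Samples the fixed-effect vector from a multivariate normal with the
#' fitted covariance, evaluates the analytic power-law trajectory on a time
#' grid per draw, and returns pointwise 2.5/97.5 percentile bands around the
#' point prediction for a given species and canopy openness.
#'
#' @param fit A converged `growmort_growth_fit`.
#' @param species Species id (one of the fitted levels).
#' @param light Canopy openness in %.
#' @param t_grid Days since planting at which to evaluate.
#' @param n_draws Number of parameter draws (default 1000).
#' @param seed RNG seed for the draws.
#' @param level Band coverage (default 0.95).
#' @return Tibble with `census_day`, `estimate`, `lower`, `upper`.
#' @export
trajectory_ci <- function(fit, species, light, t_grid, n_draws = 1000,
                          seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "growmort_growth_fit"))
  sp_levels <- fit$params$alpha_by_species$species_id
  if (!species %in% sp_levels) {
    stop("species not in the fitted model: ", species, call. = FALSE)
  }
  V <- fit$vcov_fixed
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev)))) {
    stop("fixed-effect covariance is not positive semi-definite", call. = FALSE)
  }
  fe <- fit$fixed_effects
  draws <- withr::with_seed(seed, {
    MASS::mvrnorm(n_draws, mu = fe, Sigma = V)
  })
  eval_draw <- function(par) {
    lalpha <- par[[paste0("lalpha.species_id", species)]] +
      light_effect(fit, par, species) * log(light)
    predict_size(exp(par[["lm0"]]), exp(lalpha), stats::plogis(par[["tbeta"]]), t_grid)
  }
  point <- eval_draw(fe)
  mat <- apply(draws, 1, eval_draw)
  mat <- matrix(mat, nrow = length(t_grid))
  a <- (1 - level) / 2
  tibble::tibble(
    census_day = t_grid,
    estimate = point,
    lower = apply(mat, 1, stats::quantile, probs = a),
    upper = apply(mat, 1, stats::quantile, probs = 1 - a)
  )
}

light_effect <- function(fit, par, species) {
  if (fit$species_light_interaction) {
    nm <- paste0("lalpha.species_id", species, ":log_open")
    if (nm %in% names(par)) par[[nm]] else 0
  } else {
    par[["lalpha.log_open"]]
  }
}
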