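#' Pipeline configuration
#'
#' Bundles everything a full synthetic-study run needs: the generator
#' configuration, reference size and light for demography, estimation
#' method flags, and the output directory. All defaults resolve offline.
#'
#' @param out_dir Output directory (created if absent).
#' @param sim A [sim_config()]; its `seed` drives every stochastic stage.
#' @param ref_size,ref_light Reference size (mm) and canopy openness (%)
#'   for SGR and annual mortality.
#' @param growth_method `"REML"` or `"ML"` for the reported growth fit.
#' @param light_covariate `"averaged"` or `"per_census"` openness for the
#'   mortality model.
#' @param census,trait_observations Optional tibbles (or CSV paths) to use
#'   instead of simulating.
#' @param simulate_only Stop after writing the simulated tables and truth
#'   sidecar (no model fitting).
#' @return A list of class `growmort_run_config`.
#' @export
run_config <- function(out_dir,
                       sim = sim_config(),
                       ref_size = 10,
                       ref_light = 4.5,
                       growth_method = "REML",
                       light_covariate = "averaged",
                       census = NULL,
                       trait_observations = NULL,
                       simulate_only = FALSE) {
  structure(list(
    out_dir = out_dir, sim = sim, ref_size = ref_size, ref_light = ref_light,
    growth_method = growth_method, light_covariate = light_covariate,
    census = census, trait_observations = trait_observations,
    simulate_only = simulate_only
  ), class = "growmort_run_config")
}

#' Run the full growth-mortality trade-off pipeline
#'
#' Orchestrates simulate (or load) -> growth NLME -> interval construction
#' -> mortality GLMM -> trait means -> demography -> correlation matrix and
#' SMA trade-off, writing every intermediate table as CSV plus a
#' machine-readable JSON manifest (package version, seed, configuration
#' hash and the headline estimates). Identical seed and configuration give
#' an identical manifest.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with all fitted objects and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "growmort_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  if (is.null(config$census)) {
    say("simulating population (seed ", config$sim$seed, ")")
    sim <- simulate_population(config$sim)
    census <- sim$census
    trait_obs <- sim$traits$observations
    truth <- sim$truth
    readr::write_csv(truth$species, file.path(config$out_dir, "truth_species.csv"))
    readr::write_csv(truth$individuals, file.path(config$out_dir, "truth_individuals.csv"))
    jsonlite::write_json(
      list(config = unclass(config$sim), census_re = truth$census_re),
      file.path(config$out_dir, "truth_config.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  } else {
    census <- if (is.character(config$census)) {
      read_census(config$census)
    } else {
      config$census
    }
    trait_obs <- if (is.character(config$trait_observations)) {
      readr::read_csv(config$trait_observations, show_col_types = FALSE)
    } else {
      config$trait_observations
    }
    truth <- NULL
  }
  readr::write_csv(census, file.path(config$out_dir, "census.csv"))
  if (!is.null(trait_obs)) {
    readr::write_csv(trait_obs, file.path(config$out_dir, "trait_observations.csv"))
  }
  if (isTRUE(config$simulate_only)) {
    manifest <- list(
      package_version = as.character(utils::packageVersion("growmort")),
      seed = config$sim$seed,
      config_hash = rlang::hash(unclass(config$sim)),
      stage = "simulate"
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(list(census = census, truth = truth, manifest = manifest)))
  }

  say("fitting power-law growth NLME (", config$growth_method, ")")
  growth <- fit_growth(census, method = config$growth_method)
  readr::write_csv(tidy(growth), file.path(config$out_dir, "growth_fixed_effects.csv"))

  say("building intervals and fitting cloglog mortality GLMM")
  intervals <- build_intervals(census, light = config$light_covariate)
  readr::write_csv(intervals, file.path(config$out_dir, "intervals.csv"))
  mortality <- fit_mortality(intervals)
  readr::write_csv(tidy(mortality), file.path(config$out_dir, "mortality_coefficients.csv"))

  demog <- species_demography(growth, mortality,
                              ref_size = config$ref_size,
                              ref_light = config$ref_light)
  readr::write_csv(demog, file.path(config$out_dir, "species_demography.csv"))

  trait_means <- if (!is.null(trait_obs)) estimate_trait_means(trait_obs) else NULL
  cors <- NULL
  tradeoff <- tradeoff_summary(demog)
  if (!is.null(trait_means)) {
    species_table <- trait_means |>
      dplyr::inner_join(demog |> dplyr::select("species_id", "sgr_yr", "annual_mortality"),
                        by = "species_id")
    cors <- correlation_matrix(
      species_table,
      vars = intersect(c("wood_density", "seed_mass", "leaf_cn", "sla",
                         "sgr_yr", "annual_mortality"),
                       names(species_table))
    )
    utils::write.csv(format_cor_table(cors),
                     file.path(config$out_dir, "correlation_matrix.csv"))
    readr::write_csv(cors$pairs, file.path(config$out_dir, "correlation_pairs.csv"))
  }

  manifest <- build_manifest(config, growth, mortality, demog, tradeoff, cors)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    census = census, truth = truth, growth = growth, intervals = intervals,
    mortality = mortality, trait_means = trait_means, demography = demog,
    tradeoff = tradeoff, correlations = cors, manifest = manifest
  ))
}

build_manifest <- function(config, growth, mortality, demog, tradeoff, cors) {
  g <- glance(growth)
  m <- glance(mortality)
  list(
    package_version = as.character(utils::packageVersion("growmort")),
    seed = config$sim$seed,
    config_hash = rlang::hash(unclass(config$sim)),
    growth = list(
      beta = g$beta, beta_ci = unname(growth$params$beta_ci),
      light_slope = g$light_slope, m0 = g$m0,
      alpha_min = min(growth$params$alpha_by_species$alpha),
      alpha_max = max(growth$params$alpha_by_species$alpha),
      pseudo_r2 = g$pseudo_r2, bic = g$BIC, converged = g$converged
    ),
    mortality = list(
      light_slope = m$light_slope, size_slope = m$size_slope,
      annual_mortality_min = min(demog$annual_mortality),
      annual_mortality_max = max(demog$annual_mortality),
      deaths = m$deaths, bic = m$BIC, converged = m$converged
    ),
    tradeoff = list(
      sma_slope = tradeoff$slope,
      mortality_increase_pp_per_0.1_sgr = tradeoff$mortality_increase_pp_per_0.1_sgr,
      r = tradeoff$sma$r, p_value = tradeoff$sma$p_value
    ),
    correlations = if (!is.null(cors)) {
      list(
        wd_sgr = unname(cors$r["wood_density", "sgr_yr"]),
        wd_mortality = unname(cors$r["wood_density", "annual_mortality"]),
        sgr_mortality = unname(cors$r["sgr_yr", "annual_mortality"])
      )
    }
  )
}

#' Read and write census tables
#'
#' Plain UTF-8 CSV with a header row; columns `individual_id`,
#' `species_id`, `census_day`, `diameter_mm`, `height_cm`,
#' `canopy_openness_pct`, `alive`. Doubles round-trip exactly.
#'
#' @param path CSV path.
#' @return `read_census` returns the census tibble.
#' @export
read_census <- function(path) {
  # base strtod parsing is correctly rounded, so written doubles come back
  # bit-identical
  tibble::as_tibble(utils::read.csv(path, colClasses = c(
    individual_id = "character", species_id = "character",
    census_day = "numeric", diameter_mm = "numeric", height_cm = "numeric",
    canopy_openness_pct = "numeric", alive = "integer"
  )))
}

#' @rdname read_census
#' @param census Census tibble.
#' @export
write_census <- function(census, path) {
  readr::write_csv(census, path)
  invisible(path)
}
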