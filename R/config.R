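#' Build a validated experiment configuration
#'
#' A configuration describes one batch of simulations: the food
#' environment, the competition grid, the population, the selection
#' regime and the replication settings. [run_replicates()] executes it.
#' Defaults follow the standard parameterisation: intake target
#' (500, 500), phi = 2, mu = 2, eta = 25, 150 individuals, 500
#' iterations per generation, 1000 generations, 30 replicates.
#'
#' @param experiment `"sweep"` (replicated evolutionary runs over a
#'   competition grid), `"single-generation"` (fixed-K behavioural
#'   experiment) or `"frequency-grid"`.
#' @param environment A `nutlat_environment`, a preset name, or a
#'   numeric vector of food values V.
#' @param c Competition level(s) of the grid.
#' @param intake_target,eta,n_ind,phi,mu,n_iterations,n_generations
#'   Simulation settings.
#' @param selection A [selection_config()] or a list of its arguments.
#' @param composition For fixed-K experiments: a list with `k_low`,
#'   `k_high` and `prop_high` (scalar or vector of proportions).
#' @param n_replicates,seed Replication settings.
#' @return A validated `nutlat_config` object.
#' @export
experiment_config <- function(experiment = c("sweep", "single-generation",
                                             "frequency-grid"),
                              environment = "3-food-mild",
                              c = 0, intake_target = c(500, 500),
                              eta = 25, n_ind = 150, phi = 2, mu = 2,
                              n_iterations = 500, n_generations = 1000,
                              selection = selection_config(),
                              composition = list(k_low = 0.25, k_high = 0.85,
                                                 prop_high = 0.5),
                              n_replicates = 30, seed = 1) {
  errors <- character(0)
  note <- function(msg) errors <<- base::c(errors, msg)

  experiment <- tryCatch(match.arg(experiment),
                         error = function(e) {
                           note("unknown `experiment` type")
                           NA_character_
                         })
  if (is.character(environment)) {
    environment <- tryCatch(
      environment_preset(environment, intake_target = intake_target),
      error = function(e) {
        note(sprintf("unknown environment preset %s",
                     deparse(environment)))
        NULL
      })
  } else if (is.numeric(environment)) {
    environment <- tryCatch(
      gf_environment(environment, intake_target = intake_target),
      error = function(e) {
        note(conditionMessage(e))
        NULL
      })
  }
  if (!is.null(environment) && !is_nutlat_environment(environment)) {
    note("`environment` must be a preset name, food values, or a nutlat_environment")
    environment <- NULL
  }
  if (!is.numeric(c) || length(c) == 0 || any(c < 0 | c >= 1)) {
    note("`c` must be a non-empty grid of competition levels in [0, 1)")
  }
  if (!is.numeric(n_ind) || n_ind < 2) note("`n_ind` must be at least 2")
  if (!is.numeric(phi) || phi <= 0) note("`phi` must be > 0")
  if (!is.numeric(mu) || mu <= 0) note("`mu` must be > 0")
  if (!is.numeric(eta) || eta <= 0) note("`eta` must be > 0")
  if (!is.numeric(n_iterations) || n_iterations < 1) {
    note("`n_iterations` must be at least 1")
  }
  if (!is.numeric(n_generations) || n_generations < 1) {
    note("`n_generations` must be at least 1")
  }
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    note("`n_replicates` must be at least 1")
  }
  if (is.list(selection) && !is_nutlat_selection(selection)) {
    selection <- tryCatch(do.call(selection_config, selection),
                          error = function(e) {
                            note(sprintf("invalid selection settings: %s",
                                         conditionMessage(e)))
                            NULL
                          })
  }
  if (!is.null(composition)) {
    ok <- is.list(composition) &&
      all(base::c("k_low", "k_high", "prop_high") %in% names(composition)) &&
      all(unlist(composition[base::c("k_low", "k_high")]) >= 0) &&
      all(unlist(composition[base::c("k_low", "k_high")]) <= 1) &&
      all(composition$prop_high >= 0 & composition$prop_high <= 1)
    if (!ok) note("`composition` must give k_low, k_high in [0, 1] and prop_high in [0, 1]")
  }
  if (length(errors) > 0) {
    stop("Invalid experiment configuration:\n",
         paste0("  - ", errors, collapse = "\n"), call. = FALSE)
  }
  structure(
    list(experiment = experiment, environment = environment, c = c,
         eta = eta, n_ind = as.integer(n_ind), phi = phi, mu = mu,
         n_iterations = as.integer(n_iterations),
         n_generations = as.integer(n_generations),
         selection = selection, composition = composition,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "nutlat_config"
  )
}

is_nutlat_config <- function(x) inherits(x, "nutlat_config")

#' Load and validate an experiment configuration file
#'
#' Reads a YAML (or JSON — valid JSON is valid YAML) configuration and
#' validates it through [experiment_config()], applying the documented
#' defaults for omitted fields. The file must at least name the
#' experiment type and the environment (a preset name or a `foods`
#' vector of V values). Schema violations are reported as itemised
#' errors.
#'
#' @param path Path to the configuration file.
#' @return A validated `nutlat_config`.
#' @export
load_experiment_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("Configuration file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !is.list(raw)) {
    stop(sprintf("Configuration file %s is empty or not a mapping.", path),
         call. = FALSE)
  }
  errors <- character(0)
  if (is.null(raw$experiment)) errors <- c(errors, "missing `experiment`")
  if (is.null(raw$environment)) errors <- c(errors, "missing `environment`")
  if (length(errors) > 0) {
    stop("Invalid experiment configuration:\n",
         paste0("  - ", errors, collapse = "\n"), call. = FALSE)
  }
  env <- raw$environment
  if (is.list(env)) {
    if (!is.null(env$preset)) {
      env_arg <- env$preset
    } else if (!is.null(env$foods)) {
      env_arg <- as.numeric(env$foods)
    } else {
      stop("Invalid experiment configuration:\n  - `environment` must give a `preset` or `foods`",
           call. = FALSE)
    }
    it <- if (!is.null(env$intake_target)) as.numeric(env$intake_target)
          else c(500, 500)
  } else {
    env_arg <- env
    it <- c(500, 500)
  }
  args <- list(experiment = raw$experiment, environment = env_arg,
               intake_target = it)
  for (field in c("c", "eta", "n_ind", "phi", "mu", "n_iterations",
                  "n_generations", "n_replicates", "seed")) {
    if (!is.null(raw[[field]])) args[[field]] <- unlist(raw[[field]])
  }
  if (!is.null(raw$selection)) args$selection <- raw$selection
  if (!is.null(raw$composition)) args$composition <- raw$composition
  do.call(experiment_config, args)
}

#' Execute a configuration: replicated, seeded simulations
#'
#' Runs the batch described by a `nutlat_config`: every grid point gets
#' `n_replicates` independent simulations, each with a recorded seed
#' spawned from the master seed, so a batch is exactly reproducible.
#' Per-replicate extinction is recorded in the output, never dropped.
#'
#' @param config A `nutlat_config` from [experiment_config()] or
#'   [load_experiment_config()].
#' @return A tibble of per-replicate records; its shape depends on the
#'   experiment type (see [run_competition_sweep()],
#'   [run_experiment2()], [run_frequency_grid()]).
#' @export
run_replicates <- function(config) {
  stopifnot(is_nutlat_config(config))
  switch(config$experiment,
    "sweep" = run_competition_sweep(
      c_values = config$c, environment = config$environment,
      selection = config$selection, n_generations = config$n_generations,
      n_replicates = config$n_replicates, seed = config$seed,
      eta = config$eta, n_ind = config$n_ind, phi = config$phi,
      mu = config$mu, n_iterations = config$n_iterations),
    "single-generation" = purrr::map_dfr(config$c, function(ci) {
      run_experiment2(
        c = ci, prop_high = config$composition$prop_high[1],
        n_replicates = config$n_replicates, seed = config$seed,
        environment = config$environment, eta = config$eta,
        n_ind = config$n_ind, k_low = config$composition$k_low,
        k_high = config$composition$k_high, phi = config$phi,
        mu = config$mu, n_iterations = config$n_iterations)
    }),
    "frequency-grid" = run_frequency_grid(
      c_values = config$c, prop_high = config$composition$prop_high,
      n_replicates = config$n_replicates, seed = config$seed,
      environment = config$environment, eta = config$eta,
      n_ind = config$n_ind, k_low = config$composition$k_low,
      k_high = config$composition$k_high, phi = config$phi,
      mu = config$mu, n_iterations = config$n_iterations)
  )
}
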