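#' Summarise a set of K values
#'
#' Arithmetic mean with empirical 2.5th and 97.5th percentiles, using
#' the linear-interpolation quantile convention (R type 7).
#'
#' @param values Non-empty numeric vector of K values.
#' @return A one-row tibble with `mean_k`, `k_lower`, `k_upper`.
#' @export
summarize_k <- function(values) {
  if (length(values) == 0 || any(!is.finite(values))) {
    stop("`values` must be a non-empty vector of finite K values.",
         call. = FALSE)
  }
  q <- quantile(values, c(0.025, 0.975), names = FALSE, type = 7)
  tibble::tibble(mean_k = mean(values), k_lower = q[1], k_upper = q[2])
}

# one master seed spawns one recorded seed per replicate
replicate_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n)
}

#' Single-generation experiment with two fixed latitude strategies
#'
#' The behavioural experiment: a population of fixed (non-evolving)
#' nutritional latitudes — by default half at K = 0.25 and half at
#' K = 0.85 — lives through single 500-iteration generations at a given
#' competition level, replicated independently. For each replicate the
#' per-group behavioural statistics are recorded.
#'
#' @param c Competition level.
#' @param prop_high Proportion of the population at `k_high`.
#' @param n_replicates Number of independent replicate generations.
#' @param seed Master seed; one recorded seed is spawned per replicate.
#' @param environment Food environment (default the 3-food mild preset:
#'   one balanced food flanked by V = 0.5 and V = 2).
#' @param eta Dominance steepness.
#' @param n_ind Population size.
#' @param k_low,k_high The two strategy values.
#' @param phi,mu,n_iterations As in [run_generation()].
#' @return A tibble with one row per replicate and K group: `replicate`,
#'   `seed`, `c`, `k`, `group` (`"low"`/`"high"`), `n`, `mean_fitness`,
#'   `mean_beta` (degrees), `mean_iterations_displaced`,
#'   `mean_contests_initiated`, `mean_win_rate`.
#' @export
run_experiment2 <- function(c = 0.683, prop_high = 0.5, n_replicates = 30,
                            seed = 1,
                            environment = environment_preset("3-food-mild"),
                            eta = 25, n_ind = 150, k_low = 0.25,
                            k_high = 0.85, phi = 2, mu = 2,
                            n_iterations = 500) {
  cmp <- competition_config(c = c, n_food = nrow(environment$foods),
                            n_ind = n_ind, eta = eta)
  seeds <- replicate_seeds(seed, n_replicates)
  purrr::map2_dfr(seq_len(n_replicates), seeds, function(r, s) {
    set.seed(s)
    pop <- mixed_population(n_ind, k_low = k_low, k_high = k_high,
                            prop_high = prop_high)
    res <- run_generation(pop, environment, cmp, phi = phi, mu = mu,
                          n_iterations = n_iterations)
    summarize_generation(res) |>
      dplyr::mutate(
        replicate = r, seed = s, c = !!c,
        group = dplyr::case_when(.data$k == k_low ~ "low",
                                 .data$k == k_high ~ "high",
                                 TRUE ~ NA_character_),
        .before = 1
      )
  })
}

#' Frequency-dependence grid of the two-strategy experiment
#'
#' Co-varies the proportion of high-latitude individuals and the
#' competition level, recording for each replicate the end-of-generation
#' mean fitness of each strategy, of the whole population, and the
#' relative fitness of the high-K strategy (high minus low).
#'
#' @inheritParams run_experiment2
#' @param c_values Competition levels of the grid.
#' @param prop_high Proportions of the population at `k_high`. Only
#'   proportions with at least one individual in each group yield both
#'   group means; one-strategy endpoints give `NA` for the absent group.
#' @return A tibble with one row per (`c`, `prop_high`, `replicate`):
#'   columns `mean_fitness_low`, `mean_fitness_high`,
#'   `mean_fitness_all`, `relative_fitness_high`.
#' @export
run_frequency_grid <- function(c_values = c(0.683, 0.725, 0.767),
                               prop_high = seq(0.1, 0.9, by = 0.1),
                               n_replicates = 10, seed = 1,
                               environment = environment_preset("3-food-mild"),
                               eta = 25, n_ind = 150, k_low = 0.25,
                               k_high = 0.85, phi = 2, mu = 2,
                               n_iterations = 500) {
  grid <- tidyr::expand_grid(c = c_values, prop_high = prop_high,
                             replicate = seq_len(n_replicates))
  grid$seed <- replicate_seeds(seed, nrow(grid))
  purrr::pmap_dfr(grid, function(c, prop_high, replicate, seed) {
    cmp <- competition_config(c = c, n_food = nrow(environment$foods),
                              n_ind = n_ind, eta = eta)
    set.seed(seed)
    pop <- mixed_population(n_ind, k_low = k_low, k_high = k_high,
                            prop_high = prop_high)
    res <- run_generation(pop, environment, cmp, phi = phi, mu = mu,
                          n_iterations = n_iterations)
    f_low <- mean(res$fitness[res$k == k_low])
    f_high <- mean(res$fitness[res$k == k_high])
    tibble::tibble(
      c = c, prop_high = prop_high, replicate = replicate, seed = seed,
      mean_fitness_low = f_low, mean_fitness_high = f_high,
      mean_fitness_all = mean(res$fitness),
      relative_fitness_high = f_high - f_low
    )
  })
}

#' Sweep competition levels with replicated evolutionary runs
#'
#' For each competition level, runs `n_replicates` independent
#' evolutionary simulations and records the final-generation summary of
#' K plus the extinction outcome. Extinct replicates are flagged, never
#' silently dropped.
#'
#' @inheritParams run_evolution
#' @param c_values Competition levels to sweep.
#' @param n_replicates Replicates per level.
#' @param seed Master seed (one recorded seed per replicate).
#' @param eta Dominance steepness.
#' @return A tibble with one row per (`c`, `replicate`): `seed`,
#'   `extinct`, `extinct_generation`, `n_generations`, `mean_k`,
#'   `k_lower`, `k_upper` (K summaries of the last generation lived).
#' @export
run_competition_sweep <- function(c_values, environment,
                                  selection = selection_config(),
                                  n_generations = 1000, n_replicates = 30,
                                  seed = 1, eta = 25, n_ind = 150,
                                  phi = 2, mu = 2, n_iterations = 500) {
  grid <- tidyr::expand_grid(c = c_values, replicate = seq_len(n_replicates))
  grid$seed <- replicate_seeds(seed, nrow(grid))
  purrr::pmap_dfr(grid, function(c, replicate, seed) {
    cmp <- competition_config(c = c, n_food = nrow(environment$foods),
                              n_ind = n_ind, eta = eta)
    set.seed(seed)
    traj <- run_evolution(environment, cmp, selection = selection,
                          n_generations = n_generations, n_ind = n_ind,
                          phi = phi, mu = mu, n_iterations = n_iterations)
    g <- glance(traj)
    tibble::tibble(
      c = c, replicate = replicate, seed = seed,
      extinct = g$extinct, extinct_generation = g$extinct_generation,
      n_generations = g$n_generations,
      mean_k = g$final_mean_k, k_lower = g$final_k_lower,
      k_upper = g$final_k_upper
    )
  })
}
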