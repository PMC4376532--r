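#' Configure the selection regime
#'
#' Two regimes are supported. Under `"general"` selection a generation
#' lasts a fixed number of iterations; individuals whose final fitness
#' strictly exceeds `fitness_cutoff` are eligible to breed and parents
#' are then sampled with probability proportional to fitness. If nobody
#' exceeds the cutoff the population goes extinct. Under `"truncated"`
#' selection the generation has no fixed length: the first
#' `truncation_fraction` of the population to exceed the cutoff become
#' the (equally weighted) parents, so extinction cannot occur.
#'
#' @param mode `"general"` or `"truncated"`.
#' @param fitness_cutoff Breeding threshold in (0, 1); default 0.5.
#' @param truncation_fraction Proportion of the population assigned as
#'   parents under truncated selection; default 0.1.
#' @param mutation_sd Standard deviation of the Gaussian mutation added
#'   to an inherited K; default 0.025.
#' @param max_iterations Safety cap on the length of a truncated
#'   generation; default 25000 (50 times the nominal 500).
#' @return A `nutlat_selection` object.
#' @export
selection_config <- function(mode = c("general", "truncated"),
                             fitness_cutoff = 0.5,
                             truncation_fraction = 0.1,
                             mutation_sd = 0.025,
                             max_iterations = 25000) {
  mode <- match.arg(mode)
  stopifnot(fitness_cutoff > 0, fitness_cutoff < 1,
            truncation_fraction > 0, truncation_fraction <= 1,
            mutation_sd >= 0, max_iterations >= 1)
  structure(
    list(mode = mode, fitness_cutoff = fitness_cutoff,
         truncation_fraction = truncation_fraction,
         mutation_sd = mutation_sd,
         max_iterations = as.integer(max_iterations)),
    class = "nutlat_selection"
  )
}

is_nutlat_selection <- function(x) inherits(x, "nutlat_selection")

#' Individuals eligible to breed under general selection
#'
#' Eligibility is strict: fitness must exceed the cutoff, so an
#' individual at exactly the cutoff does not breed. An empty result
#' signals extinction.
#'
#' @param generation_result A `nutlat_generation` (or any tibble with a
#'   `fitness` column).
#' @param fitness_cutoff Breeding threshold.
#' @return The eligible rows, as a tibble.
#' @export
eligible_parents_general <- function(generation_result, fitness_cutoff = 0.5) {
  tibble::as_tibble(generation_result) |>
    dplyr::filter(.data$fitness > fitness_cutoff)
}

#' Fitness-proportionate parent sampling
#'
#' Draws `n_offspring` parents independently with replacement, each
#' eligible parent chosen with probability proportional to its fitness.
#'
#' @param parents Tibble of eligible parents (columns `k`, `fitness`).
#' @param n_offspring Number of draws.
#' @return The sampled parent rows (a tibble with `n_offspring` rows).
#' @export
sample_parents_proportionate <- function(parents, n_offspring) {
  if (nrow(parents) == 0) {
    stop("No eligible parents: the population is extinct.", call. = FALSE)
  }
  idx <- sample.int(nrow(parents), n_offspring, replace = TRUE,
                    prob = parents$fitness)
  parents[idx, , drop = FALSE]
}

#' Mutate inherited nutritional latitude
#'
#' Adds independent Gaussian noise (mean 0, SD `mutation_sd`) to each
#' inherited K and clamps the result to \[0, 1\]. With clamping (rather
#' than reflection) at the bounds, K performs a bounded random walk
#' under neutrality whose stationary distribution is approximately
#' uniform away from the boundaries.
#'
#' @param parent_k Inherited K value(s) in \[0, 1\].
#' @param mutation_sd Mutation standard deviation.
#' @return Mutated K value(s) in \[0, 1\].
#' @export
mutate_k <- function(parent_k, mutation_sd = 0.025) {
  stopifnot(all(parent_k >= 0 & parent_k <= 1), mutation_sd >= 0)
  pmin(1, pmax(0, parent_k + rnorm(length(parent_k), 0, mutation_sd)))
}

#' Build the next generation under general selection
#'
#' Offspring (population size is conserved) start at the origin with
#' zeroed statistics and inherit a mutated K from fitness-proportionately
#' sampled eligible parents. Returns `NULL` when no individual exceeds
#' the cutoff — extinction is a signalled outcome, not an error.
#'
#' @param generation_result A `nutlat_generation`.
#' @param selection A [selection_config()].
#' @param n_ind Offspring count.
#' @return A new population tibble, or `NULL` on extinction.
#' @export
reproduce_general <- function(generation_result, selection = selection_config(),
                              n_ind = 150) {
  eligible <- eligible_parents_general(generation_result,
                                       selection$fitness_cutoff)
  if (nrow(eligible) == 0) return(NULL)
  chosen <- sample_parents_proportionate(eligible, n_ind)
  new_population(n_ind, k = mutate_k(chosen$k, selection$mutation_sd))
}

#' Run one generation under truncated selection
#'
#' Iterates the scheduler with no fixed generation length. After each
#' fitness phase, individuals whose fitness first exceeds the cutoff
#' join an arrival list; the generation stops once the list reaches
#' `ceiling(truncation_fraction * n_ind)` parents. When same-iteration
#' ties push the list past the target it is randomly subsampled down to
#' the target size. Parents are equally weighted.
#'
#' @inheritParams run_generation
#' @param selection A [selection_config()] with `mode = "truncated"`.
#' @return A list with elements `result` (the `nutlat_generation` at
#'   stopping time), `parents` (tibble of parent rows), and
#'   `n_iterations` (elapsed iterations).
#' @export
run_generation_truncated <- function(population, environment, competition,
                                     selection, phi = 2, mu = 2) {
  stopifnot(is_nutlat_selection(selection))
  if (selection$mode != "truncated") {
    stop("`selection$mode` must be \"truncated\".", call. = FALSE)
  }
  check_run_inputs(population, environment, competition, phi, mu)
  n_target <- as.integer(ceiling(selection$truncation_fraction *
                                   nrow(population)))
  group_k <- sort(unique(population$k))
  raw <- engine_generation(
    population$p, population$c, population$k,
    environment$foods$rail_angle,
    environment$intake_target[1], environment$intake_target[2],
    environment$initial_distance, capacity(competition), competition$eta,
    phi, mu, 0L, TRUE, selection$fitness_cutoff, n_target,
    selection$max_iterations, match(population$k, group_k) - 1L,
    length(group_k), FALSE
  )
  if (isTRUE(raw$aborted)) {
    stop(sprintf(paste0("Truncated generation did not produce %d parents ",
                        "within the safety cap of %d iterations ",
                        "(%d arrivals)."),
                 n_target, selection$max_iterations, length(raw$arrivals)),
         call. = FALSE)
  }
  result <- build_generation_result(raw, population, environment,
                                    competition, phi, mu, group_k)
  list(result = result,
       parents = result[result$id %in% raw$arrivals, , drop = FALSE],
       n_iterations = raw$n_iterations)
}

#' Evolve nutritional latitude across generations
#'
#' Runs the full evolutionary algorithm: every individual of the initial
#' generation has `init_k` (1 by default — maximal tolerance), each
#' generation lives through the scheduler, and offspring inherit a
#' mutated K from the selected parents. Under general selection a
#' generation in which nobody exceeds the fitness cutoff terminates the
#' run with an extinction flag.
#'
#' @inheritParams run_generation
#' @param selection A [selection_config()].
#' @param n_generations Number of generations.
#' @param n_ind Population size (constant across generations).
#' @param init_k Initial K of every founder.
#' @return A `nutlat_evolution` object: a tibble with one row per
#'   generation lived (`generation`, `mean_k`, `k_lower` / `k_upper` —
#'   the 2.5th / 97.5th percentiles of K, `n_parents`, `n_iterations`,
#'   `extinct`), with run settings as attributes.
#' @examples
#' env <- environment_preset("3-food-mild")
#' cmp <- competition_config(c = 0.7, n_food = 3, n_ind = 30)
#' set.seed(1)
#' run_evolution(env, cmp, n_generations = 3, n_ind = 30)
#' @export
run_evolution <- function(environment, competition,
                          selection = selection_config(),
                          n_generations = 1000, n_ind = 150, init_k = 1,
                          phi = 2, mu = 2, n_iterations = 500,
                          engine = c("fast", "reference")) {
  engine <- match.arg(engine)
  stopifnot(is_nutlat_selection(selection), n_generations >= 1)
  population <- new_population(n_ind, k = init_k)
  rows <- vector("list", n_generations)
  extinct <- FALSE
  g_last <- 0L
  for (g in seq_len(n_generations)) {
    g_last <- g
    if (selection$mode == "general") {
      res <- run_generation(population, environment, competition,
                            phi = phi, mu = mu,
                            n_iterations = n_iterations, engine = engine)
      eligible <- eligible_parents_general(res, selection$fitness_cutoff)
      n_parents <- nrow(eligible)
      iters <- attr(res, "n_iterations")
      offspring <- reproduce_general(res, selection, n_ind)
    } else {
      gen <- run_generation_truncated(population, environment, competition,
                                      selection, phi = phi, mu = mu)
      n_parents <- nrow(gen$parents)
      iters <- gen$n_iterations
      chosen <- gen$parents[sample.int(n_parents, n_ind, replace = TRUE), ]
      offspring <- new_population(n_ind,
                                  k = mutate_k(chosen$k, selection$mutation_sd))
    }
    ks <- summarize_k(population$k)
    rows[[g]] <- tibble::tibble(
      generation = g, mean_k = ks$mean_k,
      k_lower = ks$k_lower, k_upper = ks$k_upper,
      n_parents = n_parents, n_iterations = iters,
      extinct = is.null(offspring)
    )
    if (is.null(offspring)) {
      extinct <- TRUE
      break
    }
    population <- offspring
  }
  out <- dplyr::bind_rows(rows[seq_len(g_last)])
  structure(out,
            class = c("nutlat_evolution", class(out)),
            environment = environment, competition = competition,
            selection = selection, n_ind = n_ind, phi = phi, mu = mu,
            n_iterations = n_iterations, extinct = extinct,
            extinct_generation = if (extinct) g_last else NA_integer_,
            final_population = population)
}

#' @export
tidy.nutlat_evolution <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @export
glance.nutlat_evolution <- function(x, ...) {
  last <- x[nrow(x), ]
  tibble::tibble(
    n_generations = nrow(x),
    extinct = attr(x, "extinct"),
    extinct_generation = attr(x, "extinct_generation"),
    final_mean_k = last$mean_k,
    final_k_lower = last$k_lower,
    final_k_upper = last$k_upper
  )
}
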