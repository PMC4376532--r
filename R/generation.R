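#' Run one generation of the foraging model
#'
#' Executes the four-phase scheduler — Choose Food, Eat, Calculate
#' Fitness, Leave — for `n_iterations` iterations over the whole
#' population. Every phase completes for all individuals before the next
#' begins; searchers are processed in a fresh random order each
#' iteration with immediate state updates, so early contest outcomes
#' affect later ones within the same choose phase. A displaced
#' individual loses the remainder of the iteration and resumes searching
#' at the next one.
#'
#' @param population A population tibble from [new_population()] or
#'   [mixed_population()] (columns `id`, `k`, `p`, `c`).
#' @param environment A [gf_environment()].
#' @param competition A [competition_config()]; its `n_food` must match
#'   the environment.
#' @param phi Maximum amount eaten per iteration.
#' @param mu Fitness decay constant.
#' @param n_iterations Iterations in the generation (>= 0).
#' @param engine `"fast"` (compiled) or `"reference"` (naive per-agent R
#'   loop). Both follow the same random-stream discipline and produce
#'   identical trajectories for a given seed.
#' @param record_series Record per-iteration, per-K-group time series of
#'   mean fitness, mean cumulative contests initiated and win rate
#'   (fast engine only).
#' @return A `nutlat_generation` object: a tibble with one row per
#'   individual (`id`, `k`, `p`, `c`, `fitness`, `feed_events`,
#'   `beta_mean` — the per-iteration mean angular deviation from the
#'   ideal rail in degrees: the angle beta is recorded at every feed
#'   event and the sum divided by the number of iterations, so
#'   iterations spent displaced from food contribute zero —
#'   `iterations_displaced`, `contests_initiated`, `contests_involved`,
#'   `contests_won`, `win_rate` — `NA` with no contests), with the run
#'   settings and any recorded series stored as attributes.
#' @examples
#' env <- environment_preset("3-food-mild")
#' cmp <- competition_config(c = 0, n_food = 3, n_ind = 20)
#' set.seed(1)
#' run_generation(new_population(20), env, cmp, n_iterations = 50)
#' @export
run_generation <- function(population, environment, competition,
                           phi = 2, mu = 2, n_iterations = 500,
                           engine = c("fast", "reference"),
                           record_series = FALSE) {
  engine <- match.arg(engine)
  check_run_inputs(population, environment, competition, phi, mu)
  if (!is.numeric(n_iterations) || n_iterations < 0) {
    stop("`n_iterations` must be a non-negative integer.", call. = FALSE)
  }
  rails <- environment$foods$rail_angle
  it <- environment$intake_target
  cap <- capacity(competition)
  group_k <- sort(unique(population$k))

  if (engine == "fast") {
    raw <- engine_generation(
      population$p, population$c, population$k, rails, it[1], it[2],
      environment$initial_distance, cap, competition$eta, phi, mu,
      as.integer(n_iterations), FALSE, 0.5, 0L, 0L,
      match(population$k, group_k) - 1L, length(group_k), record_series
    )
  } else {
    if (record_series) {
      stop("`record_series` is only available with the fast engine.",
           call. = FALSE)
    }
    raw <- reference_generation(
      population$p, population$c, population$k, rails, it[1], it[2],
      environment$initial_distance, cap, competition$eta, phi, mu,
      as.integer(n_iterations)
    )
  }
  build_generation_result(raw, population, environment, competition,
                          phi, mu, group_k)
}

check_run_inputs <- function(population, environment, competition, phi, mu) {
  if (!is.data.frame(population) ||
      !all(c("id", "k", "p", "c") %in% names(population))) {
    stop("`population` must be a tibble with columns id, k, p, c.",
         call. = FALSE)
  }
  if (!is_nutlat_environment(environment)) {
    stop("`environment` must be a nutlat_environment.", call. = FALSE)
  }
  if (nrow(environment$foods) < 1) {
    stop("The environment must contain at least one food.", call. = FALSE)
  }
  if (!is_nutlat_competition(competition)) {
    stop("`competition` must be a nutlat_competition.", call. = FALSE)
  }
  if (competition$n_food != nrow(environment$foods)) {
    stop("`competition$n_food` does not match the number of foods in the environment.",
         call. = FALSE)
  }
  if (competition$n_ind != nrow(population)) {
    stop("`competition$n_ind` does not match the population size.",
         call. = FALSE)
  }
  stopifnot(phi > 0, mu > 0)
  invisible(TRUE)
}

build_generation_result <- function(raw, population, environment,
                                    competition, phi, mu, group_k) {
  res <- tibble::tibble(
    id = population$id,
    k = population$k,
    p = raw$p,
    c = raw$c,
    fitness = raw$fitness,
    feed_events = raw$feed_events,
    beta_mean = if (raw$n_iterations > 0) {
      (raw$beta_sum / raw$n_iterations) * 180 / pi
    } else {
      NA_real_
    },
    iterations_displaced = raw$iterations_displaced,
    contests_initiated = raw$contests_initiated,
    contests_involved = raw$contests_involved,
    contests_won = raw$contests_won,
    win_rate = ifelse(raw$contests_involved > 0,
                      raw$contests_won / raw$contests_involved, NA_real_)
  )
  series <- NULL
  if (!is.null(raw$series_fitness)) {
    n_it <- ncol(raw$series_fitness)
    series <- tidyr::expand_grid(iteration = seq_len(n_it), k = group_k) |>
      dplyr::mutate(
        mean_fitness = as.vector(raw$series_fitness),
        mean_contests_initiated = as.vector(raw$series_contests),
        win_rate = as.vector(raw$series_winrate)
      )
  }
  structure(res,
            class = c("nutlat_generation", class(res)),
            environment = environment, competition = competition,
            phi = phi, mu = mu, n_iterations = raw$n_iterations,
            series = series)
}

#' Per-iteration time series of a recorded generation
#'
#' @param x A `nutlat_generation` run with `record_series = TRUE`.
#' @return A tibble with columns `iteration`, `k`, `mean_fitness`,
#'   `mean_contests_initiated`, `win_rate` (one row per iteration and
#'   K group), or `NULL` if no series was recorded.
#' @export
generation_series <- function(x) {
  stopifnot(inherits(x, "nutlat_generation"))
  attr(x, "series")
}

#' @export
tidy.nutlat_generation <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @export
glance.nutlat_generation <- function(x, ...) {
  tibble::tibble(
    n_ind = nrow(x),
    n_iterations = attr(x, "n_iterations"),
    mean_fitness = mean(x$fitness),
    prop_breeding = mean(x$fitness > 0.5),
    total_contests = sum(x$contests_won),
    mean_beta = mean(x$beta_mean, na.rm = TRUE),
    mean_iterations_displaced = mean(x$iterations_displaced)
  )
}

#' Group means of the behavioural statistics by latitude value
#'
#' Summarises a single-generation result by K group: mean final fitness,
#' mean per-iteration angular deviation beta (degrees), mean iterations
#' displaced, mean contests initiated and mean win rate (individuals
#' with no contests excluded from the win-rate mean).
#'
#' @param x A `nutlat_generation`.
#' @return A tibble with one row per distinct K value.
#' @export
summarize_generation <- function(x) {
  stopifnot(inherits(x, "nutlat_generation"))
  tidy(x) |>
    dplyr::group_by(k) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_fitness = mean(.data$fitness),
      mean_beta = mean(.data$beta_mean, na.rm = TRUE),
      mean_iterations_displaced = mean(.data$iterations_displaced),
      mean_contests_initiated = mean(.data$contests_initiated),
      mean_win_rate = mean(.data$win_rate, na.rm = TRUE),
      .groups = "drop"
    )
}
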