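#' Plot an evolutionary trajectory of K
#'
#' Mean nutritional latitude per generation with a ribbon spanning the
#' 2.5th-97.5th percentiles of the population.
#'
#' @param object A `nutlat_evolution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nutlat_evolution <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$generation, y = .data$mean_k)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$k_lower,
                                      ymax = .data$k_upper),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Generation", y = "Nutritional latitude (K)",
                  title = "Evolution of nutritional latitude",
                  subtitle = "Ribbon: 2.5th-97.5th percentile of the population") +
    ggplot2::theme_minimal()
}

#' Plot the within-generation time series of a recorded generation
#'
#' Requires `run_generation(..., record_series = TRUE)`. Shows mean
#' fitness, mean cumulative contests initiated, and win rate over
#' iterations, by K group.
#'
#' @param object A `nutlat_generation` with a recorded series.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nutlat_generation <- function(object, ...) {
  series <- generation_series(object)
  if (is.null(series)) {
    stop("No series recorded; rerun with `record_series = TRUE`.",
         call. = FALSE)
  }
  series |>
    tidyr::pivot_longer(cols = c("mean_fitness", "mean_contests_initiated",
                                 "win_rate"),
                        names_to = "variable", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$iteration, y = .data$value,
                                 colour = factor(.data$k))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "Iteration", y = NULL, colour = "K") +
    ggplot2::theme_minimal()
}

#' Plot a competition sweep
#'
#' Mean evolved K (with across-replicate percentile band) against the
#' competition level; extinction-prone levels are marked by the
#' proportion of surviving replicates.
#'
#' @param sweep Output of [run_competition_sweep()].
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep) {
  summ <- sweep |>
    dplyr::group_by(.data$c) |>
    dplyr::summarise(
      surviving = sum(!.data$extinct),
      mean_k = mean(.data$mean_k[!.data$extinct]),
      k_lower = mean(.data$k_lower[!.data$extinct]),
      k_upper = mean(.data$k_upper[!.data$extinct]),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$c, y = .data$mean_k)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$k_lower,
                                      ymax = .data$k_upper),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$surviving)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Competition (c)", y = "Evolved K",
                  size = "Surviving\nreplicates") +
    ggplot2::theme_minimal()
}

#' Plot a frequency-dependence grid
#'
#' End-of-generation mean fitness of the low-K and high-K strategies
#' (and the whole population) against the proportion of high-K
#' individuals, one panel per competition level.
#'
#' @param grid Output of [run_frequency_grid()].
#' @return A ggplot.
#' @export
plot_frequency_grid <- function(grid) {
  grid |>
    dplyr::group_by(.data$c, .data$prop_high) |>
    dplyr::summarise(
      low = mean(.data$mean_fitness_low),
      high = mean(.data$mean_fitness_high),
      all = mean(.data$mean_fitness_all),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(cols = c("low", "high", "all"),
                        names_to = "strategy", values_to = "fitness") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$prop_high, y = .data$fitness,
                                 colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~c, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Proportion of population with high K",
                  y = "Mean end-of-generation fitness",
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}
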