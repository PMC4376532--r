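#' Construct a population of foraging individuals
#'
#' Individuals start at the origin of the nutrient space in "searching"
#' status with a given nutritional latitude K. `new_population()` builds
#' a homogeneous (or explicitly specified) population;
#' `mixed_population()` builds the two-strategy populations used in the
#' single-generation experiments, with a proportion `prop_high` of
#' individuals fixed at `k_high` and the rest at `k_low`.
#'
#' @param n_ind Population size.
#' @param k Nutritional latitude; length 1 or `n_ind`, values in \[0, 1\].
#' @return A tibble with columns `id`, `k`, `p`, `c` (one row per
#'   individual), suitable for [run_generation()].
#' @examples
#' new_population(10, k = 1)
#' mixed_population()          # 75 at K = 0.25, 75 at K = 0.85
#' @export
new_population <- function(n_ind = 150, k = 1) {
  stopifnot(n_ind >= 1)
  k <- rep_len(k, n_ind)
  if (any(!is.finite(k)) || any(k < 0 | k > 1)) {
    stop("`k` must lie in [0, 1].", call. = FALSE)
  }
  tibble::tibble(id = seq_len(n_ind), k = k, p = 0, c = 0)
}

#' @rdname new_population
#' @param k_low,k_high The two fixed latitude values.
#' @param prop_high Proportion of the population at `k_high`; the count
#'   is rounded to the nearest whole individual.
#' @export
mixed_population <- function(n_ind = 150, k_low = 0.25, k_high = 0.85,
                             prop_high = 0.5) {
  stopifnot(prop_high >= 0, prop_high <= 1)
  n_high <- round(prop_high * n_ind)
  new_population(n_ind, k = c(rep(k_low, n_ind - n_high), rep(k_high, n_high)))
}
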