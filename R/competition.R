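#' Competition intensity from food abundance
#'
#' Scarcity is controlled by the food abundance `a`; the intensity of
#' contest competition is `c = 1 - a / n_food`, i.e. one minus the
#' proportion of the population each food rail can support at a time.
#' When `a = n_food` every rail can hold the whole population and
#' competition is absent (`c = 0`).
#'
#' @param abundance_a Food abundance, in (0, `n_food`].
#' @param n_food Number of foods in the environment.
#' @return Competition level in \[0, 1).
#' @seealso [abundance_from_competition()] for the exact inverse.
#' @export
competition_level <- function(abundance_a, n_food) {
  if (any(abundance_a <= 0) || any(abundance_a > n_food)) {
    stop("`abundance_a` must lie in (0, n_food].", call. = FALSE)
  }
  1 - abundance_a / n_food
}

#' @rdname competition_level
#' @param c Competition level in \[0, 1).
#' @export
abundance_from_competition <- function(c, n_food) {
  if (any(c < 0) || any(c >= 1)) {
    stop("`c` must lie in [0, 1).", call. = FALSE)
  }
  (1 - c) * n_food
}

#' Configure contest competition
#'
#' Bundles the scarcity and dominance settings of a simulation. Exactly
#' one of `c` (competition level) or `abundance` may be given; the other
#' is derived. The per-food capacity — the real-valued number of feeding
#' slots — is `abundance * n_ind / n_food`.
#'
#' @param c Competition level in \[0, 1).
#' @param abundance Food abundance in (0, `n_food`].
#' @param n_food Number of foods (must match the environment used).
#' @param n_ind Population size, default 150.
#' @param eta Dominance steepness: how strongly the fitness difference
#'   between two contestants predicts the contest outcome. Default 25.
#' @return An object of class `nutlat_competition`.
#' @examples
#' competition_config(c = 0.683, n_food = 3)
#' @export
competition_config <- function(c = NULL, abundance = NULL, n_food,
                               n_ind = 150, eta = 25) {
  if (is.null(c) == is.null(abundance)) {
    stop("Give exactly one of `c` or `abundance`.", call. = FALSE)
  }
  stopifnot(n_food >= 1, n_ind >= 1, eta > 0)
  if (is.null(abundance)) {
    abundance <- abundance_from_competition(c, n_food)
  } else {
    c <- competition_level(abundance, n_food)
  }
  structure(
    list(c = c, abundance = abundance, n_food = as.integer(n_food),
         n_ind = as.integer(n_ind), eta = eta),
    class = "nutlat_competition"
  )
}

#' @export
print.nutlat_competition <- function(x, ...) {
  cat("<nutlat_competition>\n")
  cat(sprintf("  c = %.4g (abundance a = %.4g over %d foods)\n",
              x$c, x$abundance, x$n_food))
  cat(sprintf("  capacity = %.4g slots/food for %d individuals; eta = %g\n",
              capacity(x), x$n_ind, x$eta))
  invisible(x)
}

is_nutlat_competition <- function(x) inherits(x, "nutlat_competition")

#' Per-food feeding capacity
#'
#' The (real-valued) number of individuals a single food rail can
#' support at one time, `a * n_ind / n_food`. A food is "at capacity"
#' when its current occupancy is at least this value; the real value is
#' used directly so that e.g. 47 occupants are below a 47.55 capacity
#' while 48 are at it.
#'
#' @param cfg A [competition_config()] object.
#' @return Capacity in individuals per food (positive real).
#' @export
capacity <- function(cfg) {
  stopifnot(is_nutlat_competition(cfg))
  cfg$abundance * cfg$n_ind / cfg$n_food
}

#' Probability of winning a dominance contest
#'
#' The probability that challenger i displaces opponent j is a logistic
#' function of their fitness difference,
#' `Q_ij = 1 / (1 + exp(-eta * (f_i - f_j)))`, so `Q_ij + Q_ji = 1` and
#' equally fit contestants win with probability one half.
#'
#' @param f_i,f_j Fitness of the challenger and of the opponent, in
#'   (0, 1\]. Vectorised.
#' @param eta Dominance steepness (> 0).
#' @return Win probability/probabilities in (0, 1).
#' @export
dominance_probability <- function(f_i, f_j, eta = 25) {
  stopifnot(eta > 0)
  stats::plogis(eta * (f_i - f_j))
}

#' Draw contest outcomes
#'
#' Bernoulli draws of contest outcomes: the challenger wins each contest
#' independently with probability `q_ij`.
#'
#' @param q_ij Win probability/probabilities in \[0, 1\].
#' @param n Number of draws; defaults to `length(q_ij)`.
#' @return Logical vector, `TRUE` where the challenger wins.
#' @export
resolve_contest <- function(q_ij, n = length(q_ij)) {
  stopifnot(all(q_ij >= 0 & q_ij <= 1))
  runif(n) < rep_len(q_ij, n)
}
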