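#' Angle of a food rail
#'
#' A food is characterised by its nutrient ratio `value_v`, the amount of
#' carbohydrate per unit protein. In the nutrient plane (protein on x,
#' carbohydrate on y) the food defines a rail from the origin with angle
#' `atan(value_v)` measured counter-clockwise from the protein axis.
#' A balanced food (`value_v = 1`) bisects the positive quadrant.
#'
#' @param value_v Carbohydrate units per unit of protein; finite, > 0.
#'   Vectorised.
#' @return Rail angle(s) in radians, strictly inside (0, pi/2).
#' @examples
#' rail_angle(1)    # pi/4
#' rail_angle(c(0.5, 2))
#' @export
rail_angle <- function(value_v) {
  if (!is.numeric(value_v) || length(value_v) == 0 ||
      any(!is.finite(value_v)) || any(value_v <= 0)) {
    stop("`value_v` must be finite and strictly positive (carbohydrate per unit protein).",
         call. = FALSE)
  }
  atan(value_v)
}

#' Angle of the ideal food rail
#'
#' The ideal rail is the direction from an individual's nutritional state
#' to the intake target: the rail of a hypothetical food that would guide
#' it straight to the target. For a state exactly at the target the angle
#' is defined as 0 (the individual has no direction left to travel; its
#' appetite is 0 everywhere).
#'
#' @param p,c Protein and carbohydrate coordinates of the nutritional
#'   state(s). Vectorised.
#' @param target Intake target, numeric length 2 `(p, c)`.
#' @return Angle(s) in radians from the protein axis, via `atan2`; states
#'   past the target in one nutrient give angles outside (0, pi/2).
#' @export
ideal_angle <- function(p, c, target = c(500, 500)) {
  stopifnot(is.numeric(target), length(target) == 2, all(is.finite(target)))
  atan2(target[2] - c, target[1] - p)
}

#' Appetite under the nearest-distance rule of compromise
#'
#' The appetite A is how far along its current rail an individual would
#' eat to get as close as possible to the intake target: the scalar
#' projection of the vector to the target onto the rail direction,
#' `||V_T|| * cos(beta)` with `beta` the angle between the rail and the
#' ideal rail. Negative projections (a rail pointing away from the
#' target, e.g. past the point of nutritional compromise) are clamped to
#' zero: intake is physically non-negative, and departure is handled by
#' the leave rule rather than by "eating backwards".
#'
#' @inheritParams ideal_angle
#' @param rail Rail angle(s) in radians (see [rail_angle()]).
#' @return Non-negative appetite(s), in nutrient units.
#' @export
appetite <- function(p, c, rail, target = c(500, 500)) {
  dp <- target[1] - p
  dc <- target[2] - c
  dist <- sqrt(dp^2 + dc^2)
  beta <- abs(ideal_angle(p, c, target) - rail)
  a <- dist * cos(beta)
  # at the target the ideal angle is degenerate; appetite is 0 regardless
  a[dist == 0] <- 0
  pmax(0, a)
}

#' Move a nutritional state by one eating event
#'
#' Eating moves the state parallel to the rail of the food consumed by
#' `min(appetite, phi)`: the individual eats up to its appetite but no
#' more than the per-iteration maximum `phi`.
#'
#' @inheritParams appetite
#' @param appetite_a Appetite(s), non-negative (see [appetite()]).
#' @param phi Maximum amount eaten in one iteration (> 0).
#' @return A tibble with columns `p` and `c`: the displaced state(s).
#' @export
eat_step <- function(p, c, rail, appetite_a, phi = 2) {
  stopifnot(phi > 0, all(appetite_a >= 0))
  d <- pmin(appetite_a, phi)
  tibble::tibble(p = p + d * cos(rail), c = c + d * sin(rail))
}

#' Fitness as a function of distance to the intake target
#'
#' Fitness is `exp(-mu * D_N)` where `D_N` is the Euclidean distance to
#' the intake target expressed as a proportion of `initial_distance`, the
#' total distance an individual must travel over the simulation (origin
#' to target). Fitness is 1 exactly at the target and `exp(-mu)` at the
#' start, and depends only on distance, not direction.
#'
#' @inheritParams ideal_angle
#' @param initial_distance Normalising distance (> 0); defaults to the
#'   origin-to-target distance.
#' @param mu Fitness decay constant (> 0), default 2.
#' @return Fitness value(s) in (0, 1].
#' @export
gf_fitness <- function(p, c, target = c(500, 500),
                       initial_distance = NULL, mu = 2) {
  if (is.null(initial_distance)) initial_distance <- sqrt(sum(target^2))
  stopifnot(initial_distance > 0, mu > 0)
  d <- sqrt((target[1] - p)^2 + (target[2] - c)^2)
  exp(-mu * d / initial_distance)
}

#' Probability of spontaneously leaving a food
#'
#' An individual feeding on a rail may abandon it before satisfying its
#' appetite. The probability is
#' `(1 - K) * |alpha_ideal - alpha_f| / (pi/2) + max(0, (K*phi - A)/phi)`,
#' clamped to \[0, 1\]. The first term makes intolerant (low-K)
#' individuals leave imbalanced rails; the second makes any individual
#' leave once its appetite on the rail falls below `K * phi` — in
#' particular certain departure at the point of nutritional compromise
#' when `K = 1`.
#'
#' @param k Nutritional latitude in \[0, 1\]. Vectorised.
#' @param rail,ideal Rail angle and ideal-rail angle, radians.
#' @param appetite_a Current appetite on the rail, non-negative.
#' @param phi Maximum amount eaten per iteration (> 0).
#' @return Leave probability/probabilities in \[0, 1\].
#' @export
leave_probability <- function(k, rail, ideal, appetite_a, phi = 2) {
  stopifnot(all(k >= 0 & k <= 1), phi > 0, all(appetite_a >= 0))
  p <- (1 - k) * abs(ideal - rail) / (pi / 2) +
    pmax(0, (k * phi - appetite_a) / phi)
  pmin(1, pmax(0, p))
}
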