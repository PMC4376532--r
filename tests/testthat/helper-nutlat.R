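# Shared fixtures and independent oracles, built in code.

# Brute-force appetite oracle: the squared distance to the target along
# the rail is exactly quadratic in the displacement d, so its arg-min is
# recovered from three point evaluations — no angles, no projection
# formula shared with the implementation.
oracle_appetite <- function(p, c, rail, target = c(500, 500)) {
  f <- function(d) {
    (target[1] - (p + d * cos(rail)))^2 + (target[2] - (c + d * sin(rail)))^2
  }
  f0 <- f(0); f1 <- f(1); f2 <- f(2)
  a <- (f0 - 2 * f1 + f2) / 2
  b <- f1 - f0 - a
  max(0, -b / (2 * a))
}

# foot of the perpendicular from the target onto a rail through the origin
compromise_point <- function(rail, target = c(500, 500)) {
  u <- c(cos(rail), sin(rail))
  d <- sum(target * u)
  d * u
}

small_env <- function(foods = c(0.5, 1, 2)) gf_environment(foods)

no_competition <- function(n_ind, n_food = 3, eta = 25) {
  competition_config(c = 0, n_food = n_food, n_ind = n_ind, eta = eta)
}
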