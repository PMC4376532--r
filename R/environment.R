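#' Define a nutrient environment
#'
#' An environment is a set of food rails plus the intake target. Each
#' food is given by its nutrient ratio V (carbohydrate per unit protein);
#' its rail angle is derived with [rail_angle()]. The initial distance —
#' origin to intake target — normalises the fitness function.
#'
#' @param foods Numeric vector of food values V (> 0), one per food.
#' @param intake_target Intake target coordinates `(p, c)`, both > 0.
#' @return An object of class `nutlat_environment`: a list with elements
#'   `foods` (tibble with `value_v`, `rail_angle`), `intake_target` and
#'   `initial_distance`.
#' @examples
#' gf_environment(c(0.5, 1, 2))
#' @export
gf_environment <- function(foods, intake_target = c(500, 500)) {
  if (!is.numeric(intake_target) || length(intake_target) != 2 ||
      any(!is.finite(intake_target)) || any(intake_target <= 0)) {
    stop("`intake_target` must be two finite, strictly positive coordinates.",
         call. = FALSE)
  }
  food_tbl <- tibble::tibble(
    value_v = as.numeric(foods),
    rail_angle = rail_angle(foods)
  )
  structure(
    list(
      foods = food_tbl,
      intake_target = as.numeric(intake_target),
      initial_distance = sqrt(sum(intake_target^2))
    ),
    class = "nutlat_environment"
  )
}

#' @export
print.nutlat_environment <- function(x, ...) {
  cat("<nutlat_environment>\n")
  cat("  intake target: (", x$intake_target[1], ", ", x$intake_target[2],
      "), initial distance ", format(x$initial_distance, digits = 6), "\n",
      sep = "")
  cat("  foods (V):", paste(format(x$foods$value_v), collapse = ", "), "\n")
  invisible(x)
}

is_nutlat_environment <- function(x) inherits(x, "nutlat_environment")

# Named food-environment presets. The figure panels of the source model
# draw foods from the pool {0.0625, 0.5, 1, 2, 16}; these named
# combinations are the package's documented interpretations.
.environment_presets <- list(
  "3-food-mild"          = c(0.5, 1, 2),
  "3-food-extreme"       = c(0.0625, 1, 16),
  "2-food-mild"          = c(1, 2),
  "2-food-severe"        = c(1, 16),
  "2-food-complementary-mild"    = c(0.5, 2),
  "2-food-complementary-extreme" = c(0.0625, 16)
)

#' Named food-environment presets
#'
#' Convenience constructors for the food environments used throughout the
#' packaged experiments. "Mild" environments use foods with a 2:1
#' carbohydrate:protein imbalance, "extreme"/"severe" ones a 16:1
#' imbalance; 3-food environments always include a balanced food (V = 1)
#' flanked by two complementary imbalanced foods, 2-food environments
#' pair a balanced food with a single imbalanced one, and the
#' complementary presets contain two imbalanced foods whose rails
#' subtend the intake target.
#'
#' @param name One of `"3-food-mild"`, `"3-food-extreme"`,
#'   `"2-food-mild"`, `"2-food-severe"`, `"2-food-complementary-mild"`,
#'   `"2-food-complementary-extreme"`.
#' @param intake_target Passed to [gf_environment()].
#' @return A `nutlat_environment`.
#' @export
environment_preset <- function(name = names(.environment_presets),
                               intake_target = c(500, 500)) {
  name <- match.arg(name)
  gf_environment(.environment_presets[[name]], intake_target = intake_target)
}
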