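#' Construct a nutrient vector
#'
#' A nutrient vector holds the per-100 g content of the four modeled
#' nutrients — total fat, protein, carbohydrate and sodium — plus optional
#' water and ash. All values are grams per 100 g; sodium too is carried in
#' g/100 g internally (label output converts to mg).
#'
#' When both `water` and `ash` are supplied the proximate sum
#' fat + protein + carbohydrate + water + ash may not exceed 100 g by more
#' than `tolerance` (measurement noise allowance).
#'
#' @param fat,protein,carbohydrate,sodium grams per 100 g, non-negative.
#' @param water,ash optional grams per 100 g.
#' @param tolerance allowed excess of the proximate sum over 100 g.
#' @return a named numeric vector of class `"nutrient_vector"` with
#'   components `fat`, `protein`, `carbohydrate`, `sodium`, `water`, `ash`
#'   (the last two `NA` when absent).
#' @export
#' @examples
#' nutrient_vector(fat = 0.8, protein = 7.9, carbohydrate = 77.2,
#'                 sodium = 0.002, water = 13.3, ash = 0.6)
nutrient_vector <- function(fat = 0, protein = 0, carbohydrate = 0, sodium = 0,
                            water = NA_real_, ash = NA_real_, tolerance = 0.5) {
  x <- c(fat = as.numeric(fat), protein = as.numeric(protein),
         carbohydrate = as.numeric(carbohydrate), sodium = as.numeric(sodium),
         water = as.numeric(water), ash = as.numeric(ash))
  present <- !is.na(x)
  if (any(x[present] < 0))
    stop_dishlabel("validation_error", "negative nutrient value in ",
                   paste(names(x)[present & x < 0], collapse = ", "))
  if (!is.na(x["water"]) && !is.na(x["ash"])) {
    s <- sum(x[c("fat", "protein", "carbohydrate", "water", "ash")])
    if (s > 100 + tolerance)
      stop_dishlabel("validation_error", sprintf(
        "proximate sum %.2f g exceeds 100 g by more than %.2f g", s, tolerance))
  }
  structure(x, class = "nutrient_vector")
}

#' @export
print.nutrient_vector <- function(x, ...) {
  cat("Nutrients (g/100 g):\n")
  v <- unclass(x)
  for (nm in names(v))
    if (!is.na(v[[nm]])) cat(sprintf("  %-12s %9.4f\n", nm, v[[nm]]))
  invisible(x)
}

#' Coerce to a nutrient vector
#'
#' @param x a named numeric vector or list with any of the fields
#'   `fat`, `protein`, `carbohydrate`, `sodium`, `water`, `ash`.
#' @param ... passed to [nutrient_vector()].
#' @return a `"nutrient_vector"`.
#' @export
as_nutrient_vector <- function(x, ...) {
  if (inherits(x, "nutrient_vector")) return(x)
  x <- as.list(x)
  unknown <- setdiff(names(x), PROXIMATES)
  if (length(unknown))
    stop_dishlabel("validation_error", "unknown nutrient field(s): ",
                   paste(unknown, collapse = ", "))
  do.call(nutrient_vector, c(x, list(...)))
}

# The four modeled nutrients as a plain named numeric (internal workhorse).
macros <- function(x) {
  v <- unclass(x)[MACRONUTRIENTS]
  v[is.na(v)] <- 0
  v
}

zero_macros <- function() setNames(numeric(4), MACRONUTRIENTS)

#' Carbohydrate by difference
#'
#' Estimates carbohydrate as
#' `total_mass - water - ash - protein - fat`, the proximate-difference rule
#' used when carbohydrate is not measured directly. Small negative results
#' (down to `-tolerance`) are treated as measurement noise and clamped to 0
#' with a warning; larger deficits indicate inconsistent proximates and are
#' an error.
#'
#' @param total_mass,water,ash,protein,fat grams (all non-negative).
#' @param tolerance clamping band in grams, default 0.5.
#' @return carbohydrate in grams.
#' @export
#' @examples
#' carbohydrate_by_difference(100, 70, 1, 10, 5) # 14
carbohydrate_by_difference <- function(total_mass, water, ash, protein, fat,
                                       tolerance = 0.5) {
  args <- c(total_mass = total_mass, water = water, ash = ash,
            protein = protein, fat = fat)
  if (any(!is.finite(args)) || any(args < 0))
    stop_dishlabel("validation_error",
                   "all proximate arguments must be finite and >= 0")
  carb <- total_mass - water - ash - protein - fat
  if (carb < -tolerance)
    stop_dishlabel("inconsistent_proximates_error", sprintf(
      "water + ash + protein + fat = %.4f g exceeds total mass %.4f g by %.4f g",
      water + ash + protein + fat, total_mass, -carb))
  if (carb < 0) {
    warning(sprintf(
      "carbohydrate by difference %.4f g within -%.2f g tolerance; clamped to 0",
      carb, tolerance), call. = FALSE)
    carb <- 0
  }
  carb
}
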