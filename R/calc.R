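#' Construct a dish (recipe)
#'
#' @param name dish name.
#' @param method cooking method (any label [normalize_method()] accepts).
#' @param ingredients data.frame (or list of lists) with columns `food`
#'   (name or id), `raw_mass_g` (as-purchased grams), and optionally
#'   `edible_fraction` (override in (0, 1]), `subclass`,
#'   `general_category` (declared classification for fallback resolution).
#' @param seasonings data.frame or list of lists with `kind`, `mass_g`.
#' @param cooked_weight_g optional measured cooked weight (> 0). When
#'   absent the cooked weight is estimated from the raw-to-cooked ratio of
#'   the main ingredient.
#' @return a list of class `"dish"`.
#' @export
dish <- function(name, method, ingredients, seasonings = NULL,
                 cooked_weight_g = NULL) {
  if (!is.data.frame(ingredients)) {
    ingredients <- do.call(rbind, lapply(ingredients, function(l) {
      data.frame(food = l$food, raw_mass_g = l$raw_mass_g,
                 edible_fraction = l$edible_fraction %||% NA_real_,
                 subclass = l$subclass %||% NA_character_,
                 general_category = l$general_category %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }
  for (col in c("edible_fraction", "subclass", "general_category"))
    if (!col %in% names(ingredients)) ingredients[[col]] <- NA
  if (is.null(ingredients) || nrow(ingredients) < 1)
    stop_dishlabel("validation_error", "a dish needs at least one ingredient")
  if (any(ingredients$raw_mass_g < 0))
    stop_dishlabel("validation_error", "raw_mass_g must be >= 0")
  ef <- ingredients$edible_fraction
  if (any(!is.na(ef) & (ef <= 0 | ef > 1)))
    stop_dishlabel("validation_error", "edible_fraction override outside (0, 1]")
  if (!is.null(cooked_weight_g) && (!is.finite(cooked_weight_g) ||
                                    cooked_weight_g <= 0))
    stop_dishlabel("validation_error", "measured cooked weight must be > 0")
  if (is.data.frame(seasonings) && nrow(seasonings) == 0) seasonings <- NULL
  structure(list(name = as.character(name),
                 method = normalize_method(method),
                 ingredients = ingredients,
                 seasonings = seasonings,
                 cooked_weight_g = cooked_weight_g),
            class = "dish")
}

#' Read a recipe JSON file
#'
#' Expected layout:
#' `{name, cooking_method, ingredients:[{food, raw_mass_g, edible_fraction?,
#' subclass?, general_category?}], seasonings:[{kind, mass_g}],
#' cooked_weight_g?}`.
#'
#' @param path JSON file path.
#' @return a [dish()].
#' @export
read_recipe <- function(path) {
  r <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  dish(name = r$name, method = r$cooking_method,
       ingredients = r$ingredients,
       seasonings = r$seasonings,
       cooked_weight_g = r$cooked_weight_g)
}

#' Sum nutrients over resolved recipe lines
#'
#' Field-wise sum of per-100 g nutrient content times edible raw mass:
#' `sum_i nutrients_i x edible_mass_i / 100`, in absolute grams.
#'
#' @param lines data.frame with the four nutrient columns (g/100 g) and
#'   `edible_mass_g`.
#' @return named numeric of absolute grams for the modeled nutrients.
#' @export
sum_nutrients <- function(lines) {
  total <- zero_macros()
  if (is.null(lines) || nrow(lines) == 0) return(total)
  for (nut in MACRONUTRIENTS)
    total[nut] <- sum(lines[[nut]] * lines$edible_mass_g / 100)
  total
}

#' Energy of a per-100 g nutrient vector
#'
#' Label energy from per-gram conversion factors. Defaults follow the
#' Chinese nutrition-labeling convention: protein 17, fat 37, carbohydrate
#' 17 kJ/g. Atwater-style kcal factors (protein 4, fat 9, carbohydrate 4)
#' can be supplied with `unit = "kcal"`; kJ and kcal are interconverted at
#' 4.184 kJ/kcal.
#'
#' @param nv named numeric with `fat`, `protein`, `carbohydrate`
#'   (g per 100 g); negative values are an error.
#' @param factors named per-gram energy factors in `unit`.
#' @param unit unit the factors are expressed in, `"kJ"` or `"kcal"`.
#' @return named numeric `c(kJ =, kcal =)` per 100 g.
#' @export
#' @examples
#' energy_of(c(fat = 0, protein = 10, carbohydrate = 0)) # 170 kJ
energy_of <- function(nv, factors = c(protein = 17, fat = 37, carbohydrate = 17),
                      unit = c("kJ", "kcal")) {
  unit <- match.arg(unit)
  vals <- unlist(nv)[names(factors)]
  vals[is.na(vals)] <- 0
  if (any(vals < 0))
    stop_dishlabel("domain_error", "nutrient amounts must be >= 0")
  e <- sum(factors * vals)
  if (unit == "kJ") c(kJ = e, kcal = e / 4.184) else c(kJ = e * 4.184, kcal = e)
}

#' Default nutrient reference values (NRV)
#'
#' Daily reference amounts used for label NRV percentages: energy 8400 kJ,
#' protein 60 g, fat 60 g, carbohydrate 300 g, sodium 2000 mg. Fully
#' configurable.
#'
#' @return named numeric.
#' @export
default_nrv <- function() {
  c(energy_kj = 8400, protein_g = 60, fat_g = 60,
    carbohydrate_g = 300, sodium_mg = 2000)
}

#' NRV percentages of a nutrient vector
#'
#' Field-wise `100 x amount / reference` after harmonizing units (sodium is
#' converted from g to mg before division).
#'
#' @param nv named numeric of nutrient amounts in grams (per 100 g or per
#'   dish, depending on the basis you intend).
#' @param ref reference amounts, see [default_nrv()].
#' @return named numeric of percentages for the four modeled nutrients.
#' @export
#' @examples
#' nrv_percent(c(fat = 0, protein = 30, carbohydrate = 0, sodium = 1))
nrv_percent <- function(nv, ref = default_nrv()) {
  need <- c("protein_g", "fat_g", "carbohydrate_g", "sodium_mg")
  if (any(!need %in% names(ref)) || any(!is.finite(ref[need])) ||
      any(ref[need] <= 0))
    stop_dishlabel("config_error",
                   "NRV reference must be positive for ",
                   paste(need, collapse = ", "))
  v <- unlist(nv)[MACRONUTRIENTS]
  v[is.na(v)] <- 0
  c(fat = 100 * v[["fat"]] / ref[["fat_g"]],
    protein = 100 * v[["protein"]] / ref[["protein_g"]],
    carbohydrate = 100 * v[["carbohydrate"]] / ref[["carbohydrate_g"]],
    sodium = 100 * (v[["sodium"]] * 1000) / ref[["sodium_mg"]])
}

#' Compute the nutrition label of a dish
#'
#' The engine implements the mass-conservation reading of the calculation
#' model: nutrients are conserved from the raw edible inputs to the cooked
#' dish, then divided by the cooked weight. With an estimated cooked weight
#' (raw input mass / raw-to-cooked ratio) this reproduces the one-line
#' formula "raw content x ratio" exactly for single-ingredient dishes.
#'
#' Per recipe line: nutrients = resolved per-100 g content x edible raw
#' mass / 100, multiplied by the applicable (category, method, nutrient)
#' correction factor when a correction model is supplied. Seasonings add
#' fat (oil, scaled by the uptake fraction), sodium (salt, soy sauce,
#' chicken essence) and optionally sugar carbohydrate to the totals. The
#' cooked weight is the measured weight when given, otherwise total raw
#' input mass (edible ingredients + seasonings) divided by the main
#' ingredient's ratio, where the main ingredient is the line with the
#' largest edible raw mass.
#'
#' @param dish a [dish()].
#' @param db a [composition_db()].
#' @param ratios a `"ratio_table"`; default the packaged table.
#' @param corrections optional [correction_model()] or factors data.frame
#'   (`category,method,nutrient,factor`); absent factors count as 1.
#' @param seasoning_config see [default_seasonings()].
#' @param nrv reference amounts, see [default_nrv()].
#' @param energy_factors,energy_unit passed to [energy_of()].
#' @param oil_uptake oil fat uptake fraction, default 1.
#' @param sugar_carbohydrate include sugar's carbohydrate contribution
#'   (default `TRUE`).
#' @param assume_unity_ratio fall back to ratio 1 with a warning when the
#'   ratio table has no entry for the main ingredient.
#' @param nrv_basis compute NRV% from the per-100 g values (`"per100g"`,
#'   label default) or from whole-dish totals (`"total"`).
#' @return an object of class `"nutrition_label"` with elements `totals`
#'   (absolute g), `per_100g`, `cooked_weight_g`, `weight_source`
#'   (`"measured"` or `"estimated"`), `energy` (kJ and kcal per 100 g),
#'   `nrv_percent`, `corrected`, `applied_factors`, `seasoning_added` and
#'   `resolutions`.
#' @export
compute_label <- function(dish, db, ratios = NULL, corrections = NULL,
                          seasoning_config = default_seasonings(),
                          nrv = default_nrv(),
                          energy_factors = c(protein = 17, fat = 37,
                                             carbohydrate = 17),
                          energy_unit = "kJ",
                          oil_uptake = 1, sugar_carbohydrate = TRUE,
                          assume_unity_ratio = FALSE,
                          nrv_basis = c("per100g", "total")) {
  stopifnot(inherits(dish, "dish"), inherits(db, "composition_db"))
  nrv_basis <- match.arg(nrv_basis)
  if (is.null(ratios)) ratios <- load_ratio_table()

  ing <- dish$ingredients
  res <- vector("list", nrow(ing))
  lines <- data.frame(food = ing$food, edible_mass_g = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ing))) {
    res[[i]] <- resolve_ingredient(
      ing$food[i], db,
      subclass = if (!is.na(ing$subclass[i])) ing$subclass[i],
      general_category = if (!is.na(ing$general_category[i]))
        ing$general_category[i])
    ef <- if (!is.na(ing$edible_fraction[i])) ing$edible_fraction[i]
          else res[[i]]$edible_fraction %||% 1
    lines$edible_mass_g[i] <- ing$raw_mass_g[i] * ef
    for (nut in MACRONUTRIENTS) lines[[nut]][i] <- macros(res[[i]]$nutrients)[[nut]]
  }

  # per-line correction factors, keyed (category, method, nutrient)
  applied <- NULL
  if (!is.null(corrections)) {
    for (i in seq_len(nrow(lines))) {
      for (nut in MACRONUTRIENTS) {
        f <- lookup_factor(corrections,
                           category = res[[i]]$general_category,
                           subclass = res[[i]]$subclass,
                           method = dish$method, nutrient = nut)
        if (f != 1) {
          lines[[nut]][i] <- lines[[nut]][i] * f
          applied <- rbind(applied, data.frame(
            food = lines$food[i], method = dish$method, nutrient = nut,
            factor = f, stringsAsFactors = FALSE))
        }
      }
    }
  }

  totals <- sum_nutrients(lines)
  sea <- seasoning_nutrients(dish$seasonings, seasoning_config, oil_uptake)
  sea["protein"] <- 0                    # seasoning additions: fat, sodium, sugar carb
  if (!sugar_carbohydrate) sea["carbohydrate"] <- 0
  totals <- totals + sea

  sea_mass <- if (is.null(dish$seasonings)) 0 else {
    s <- dish$seasonings
    if (is.data.frame(s)) sum(s$mass_g) else sum(vapply(s, function(x)
      as.numeric(x$mass_g), numeric(1)))
  }

  if (!is.null(dish$cooked_weight_g)) {
    w <- dish$cooked_weight_g
    source <- "measured"
    ratio_used <- NULL
  } else {
    main <- which.max(lines$edible_mass_g)
    key <- res[[main]]$subclass %||% res[[main]]$general_category
    r <- lookup_ratio(key, dish$method, ratios, assume_unity = assume_unity_ratio)
    w <- estimate_cooked_weight(sum(lines$edible_mass_g) + sea_mass, r$ratio)
    source <- "estimated"
    ratio_used <- r
  }
  if (w <= 0)
    stop_dishlabel("degenerate_dish_error", "cooked weight is 0")

  per100 <- totals / w * 100
  energy <- energy_of(per100, factors = energy_factors, unit = energy_unit)
  basis_vec <- if (nrv_basis == "per100g") per100 else totals
  nrvp <- nrv_percent(basis_vec, nrv)
  basis_energy <- if (nrv_basis == "per100g") energy[["kJ"]]
                  else energy[["kJ"]] * w / 100
  nrvp <- c(energy = 100 * basis_energy / nrv[["energy_kj"]], nrvp)

  structure(list(
    dish = dish$name, method = dish$method,
    totals = totals, per_100g = per100,
    cooked_weight_g = w, weight_source = source, ratio_used = ratio_used,
    energy = energy, nrv_percent = nrvp, nrv_basis = nrv_basis,
    corrected = !is.null(applied) && nrow(applied) > 0,
    applied_factors = applied, seasoning_added = sea,
    resolutions = vapply(res, `[[`, character(1), "level")
  ), class = "nutrition_label")
}

#' @export
print.nutrition_label <- function(x, ...) {
  cat(sprintf("Nutrition label: %s (%s)\n", x$dish, x$method))
  cat(sprintf("Cooked weight: %.1f g (%s)%s\n", x$cooked_weight_g,
              x$weight_source,
              if (x$corrected) "; cooking-method corrections applied" else ""))
  cat(sprintf("%-16s %12s %8s\n", "", "Per 100 g", "NRV%"))
  cat(sprintf("%-16s %10.0f kJ %7.0f\n", "Energy", x$energy[["kJ"]],
              round_half_up(x$nrv_percent[["energy"]])))
  for (nut in c("protein", "fat", "carbohydrate")) {
    cat(sprintf("%-16s %11.1f g %7.0f\n",
                paste0(toupper(substring(nut, 1, 1)), substring(nut, 2)),
                round_half_up(x$per_100g[[nut]], 1),
                round_half_up(x$nrv_percent[[nut]])))
  }
  cat(sprintf("%-16s %10.0f mg %7.0f\n", "Sodium",
              round_half_up(x$per_100g[["sodium"]] * 1000),
              round_half_up(x$nrv_percent[["sodium"]])))
  invisible(x)
}

#' Serialize a nutrition label to JSON
#'
#' @param label a `"nutrition_label"`.
#' @param path output path, or `NULL` to return the JSON string.
#' @return `path` (invisibly) or a JSON string.
#' @export
write_label <- function(label, path = NULL) {
  stopifnot(inherits(label, "nutrition_label"))
  out <- list(
    dish = label$dish, method = label$method,
    cooked_weight_g = label$cooked_weight_g,
    weight_source = label$weight_source,
    totals_g = as.list(label$totals),
    per_100g = as.list(label$per_100g),
    energy_per_100g = as.list(label$energy),
    nrv_percent = as.list(label$nrv_percent),
    nrv_basis = label$nrv_basis,
    corrected = label$corrected
  )
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
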