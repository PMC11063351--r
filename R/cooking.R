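#' Canonical cooking methods
#'
#' The closed set of cooking-method tokens the package recognizes.
#' @return character vector of method tokens.
#' @export
cooking_methods <- function() {
  c("steaming", "boiling", "stir_frying", "deep_frying",
    "roasting", "stewing", "quick_boiling")
}

#' Normalize a cooking-method label
#'
#' Maps printed method labels to canonical tokens: case, hyphen/space
#' variants and parenthetical qualifiers are stripped, so
#' `"Stewing (with soy sauce)"`, `"Deep frying"` and `"Deep-frying"`
#' normalize to `"stewing"` and `"deep_frying"`.
#'
#' @param x character vector of method labels.
#' @return character vector of canonical tokens.
#' @export
#' @examples
#' normalize_method(c("Stewing (with soy sauce)", "Quick-boiling"))
normalize_method <- function(x) {
  y <- tolower(trimws(as.character(x)))
  y <- gsub("\\(.*?\\)", "", y)        # drop qualifiers like "(with soy sauce)"
  y <- gsub("[^a-z]+", "_", y)
  y <- gsub("^_+|_+$", "", y)
  bad <- !(y %in% cooking_methods())
  if (any(bad))
    stop_dishlabel("validation_error", "unknown cooking method(s): ",
                   paste(unique(x[bad]), collapse = ", "))
  y
}

#' Load a raw-to-cooked ratio table
#'
#' A ratio is raw edible mass divided by cooked dish mass for a (food,
#' cooking method) pair: values below 1 mean the dish gains mass on cooking
#' (e.g. rice absorbing water), values above 1 mean it loses mass. By
#' default the packaged table of 44 measured dishes is loaded.
#'
#' @param path CSV with columns `category,subclass,dish_name,method,ratio`,
#'   or `NULL` for the packaged table.
#' @return data.frame of class `"ratio_table"` with the printed method kept
#'   in `method_label` and the canonical token in `method`.
#' @export
load_ratio_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "raw_cooked_ratios.csv",
                        package = "dishlabel", mustWork = TRUE)
  df <- if (is.data.frame(path)) path
        else read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  as_ratio_table(df)
}

#' Coerce a data.frame to a ratio table
#'
#' @param df data.frame with columns
#'   `category,subclass,dish_name,method,ratio`.
#' @return a `"ratio_table"` data.frame.
#' @export
as_ratio_table <- function(df) {
  need <- c("category", "subclass", "dish_name", "method", "ratio")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_dishlabel("schema_error", "ratio table missing column(s): ",
                   paste(missing, collapse = ", "))
  df$ratio <- as.numeric(df$ratio)
  if (any(!is.finite(df$ratio)) || any(df$ratio <= 0))
    stop_dishlabel("validation_error", "every raw-to-cooked ratio must be > 0")
  df$method_label <- as.character(df$method)
  df$method <- normalize_method(df$method)
  class(df) <- c("ratio_table", "data.frame")
  df
}

#' Look up a raw-to-cooked ratio
#'
#' Matches `category_or_subclass` (case-insensitively) against the table's
#' `subclass` then `category` column, restricted to the given method. When
#' several dishes share the key their ratios are averaged arithmetically
#' and the contributing dish names are returned.
#'
#' @param category_or_subclass food key, e.g. `"rice"` or `"potato"`.
#' @param method cooking method (any label [normalize_method()] accepts).
#' @param table a `"ratio_table"`; default the packaged table.
#' @param assume_unity if `TRUE`, a missing key yields ratio 1 with a
#'   warning instead of a missing-ratio error.
#' @return list of class `"raw_cooked_ratio"`: `ratio`, `dishes`, `n`,
#'   `assumed`.
#' @export
#' @examples
#' lookup_ratio("rice", "steaming")$ratio # 0.49
lookup_ratio <- function(category_or_subclass, method,
                         table = load_ratio_table(), assume_unity = FALSE) {
  if (!inherits(table, "ratio_table")) table <- as_ratio_table(table)
  method <- normalize_method(method)
  key <- tolower(category_or_subclass)
  idx <- which(tolower(table$subclass) == key & table$method == method)
  if (!length(idx))
    idx <- which(tolower(table$category) == key & table$method == method)
  if (!length(idx)) {
    if (!assume_unity)
      stop_dishlabel("missing_ratio_error", sprintf(
        "no raw-to-cooked ratio for (%s, %s)", category_or_subclass, method))
    warning(sprintf("no ratio for (%s, %s); assuming 1.0",
                    category_or_subclass, method), call. = FALSE)
    return(structure(list(ratio = 1, dishes = character(0), n = 0L,
                          assumed = TRUE), class = "raw_cooked_ratio"))
  }
  structure(list(ratio = mean(table$ratio[idx]),
                 dishes = table$dish_name[idx],
                 n = length(idx), assumed = FALSE),
            class = "raw_cooked_ratio")
}

#' Estimate cooked weight from raw input mass
#'
#' Inverts the ratio definition (ratio = raw edible mass / cooked mass):
#' cooked weight = raw input mass / ratio.
#'
#' @param total_raw_input_mass grams of raw edible input (ingredients plus
#'   seasonings).
#' @param ratio raw-to-cooked ratio, > 0.
#' @return estimated cooked weight in grams.
#' @export
estimate_cooked_weight <- function(total_raw_input_mass, ratio) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 0))
    stop_dishlabel("domain_error", "ratio must be > 0")
  if (any(total_raw_input_mass < 0))
    stop_dishlabel("domain_error", "mass must be >= 0")
  total_raw_input_mass / ratio
}

#' Default seasoning composition
#'
#' Per-100 g nutrient content of the seasonings weighed into dishes. The
#' defaults follow standard reference compositions: refined oil 99.9 g
#' fat/100 g; table salt 39.3 g sodium/100 g (NaCl stoichiometry); soy
#' sauce 5.8 g sodium/100 g; white sugar 99.9 g carbohydrate/100 g; chicken
#' essence 20 g sodium/100 g; vinegar and fermented curd contribute none of
#' the modeled nutrients. All values are configurable via
#' [read_seasoning_config()] or by editing the returned list.
#'
#' @return named list mapping seasoning kind to a per-100 g nutrient list.
#' @export
default_seasonings <- function() {
  list(
    oil = list(fat = 99.9),
    salt = list(sodium = 39.3),
    soy_sauce = list(sodium = 5.8),
    sugar = list(carbohydrate = 99.9),
    vinegar = list(),
    chicken_essence = list(sodium = 20),
    fermented_curd = list()
  )
}

#' Read a seasoning composition config
#'
#' @param path YAML or JSON file mapping seasoning kind to per-100 g
#'   nutrient content, e.g. `oil: {fat: 99.9}`.
#' @return named list in the [default_seasonings()] layout.
#' @export
read_seasoning_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(cfg, as.list)
}

#' Nutrients contributed by seasonings
#'
#' Sums the absolute nutrient masses added by weighed seasonings: fat from
#' oil (scaled by the oil uptake fraction), sodium from salt, soy sauce and
#' chicken essence, carbohydrate from sugar. The uptake fraction defaults
#' to 1 — frying oil not fully absorbed by the food is still counted into
#' the dish.
#'
#' @param seasonings data.frame or list of lists with fields `kind` and
#'   `mass_g` (masses >= 0).
#' @param config seasoning composition, see [default_seasonings()].
#' @param oil_uptake fraction of oil fat retained in the dish, in `[0, 1]`.
#' @return named numeric of absolute grams for the four modeled nutrients.
#' @export
#' @examples
#' seasoning_nutrients(data.frame(kind = "salt", mass_g = 5))["sodium"] # 1.965
seasoning_nutrients <- function(seasonings, config = default_seasonings(),
                                oil_uptake = 1) {
  total <- zero_macros()
  if (is.null(seasonings) || length(seasonings) == 0) return(total)
  if (is.data.frame(seasonings))
    seasonings <- lapply(seq_len(nrow(seasonings)),
                         function(i) as.list(seasonings[i, ]))
  for (s in seasonings) {
    kind <- as.character(s$kind)
    mass <- as.numeric(s$mass_g)
    if (is.na(mass) || mass < 0)
      stop_dishlabel("validation_error", "seasoning mass must be >= 0")
    if (!kind %in% names(config))
      stop_dishlabel("config_error", "unknown seasoning kind: ", kind)
    comp <- config[[kind]]
    for (nut in intersect(names(comp), MACRONUTRIENTS)) {
      contrib <- as.numeric(comp[[nut]]) * mass / 100
      if (kind == "oil" && nut == "fat") contrib <- contrib * oil_uptake
      total[nut] <- total[nut] + contrib
    }
  }
  total
}
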