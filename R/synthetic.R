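#' Built-in subclass composition targets for synthetic data
#'
#' Typical raw, edible-portion macronutrient contents (g/100 g) for a small
#' set of common ingredient subclasses, with generating standard
#' deviations. These parameterize the synthetic composition-table
#' generator; they are round reference-style values, not measurements.
#'
#' @return data.frame with `general_category, subclass, edible_fraction`
#'   and per-nutrient `*_mean` / `*_sd` columns.
#' @export
synthetic_subclass_targets <- function() {
  df <- read.csv(text = "general_category,subclass,edible_fraction,fat_mean,protein_mean,carbohydrate_mean,sodium_mean
grain,rice,1.00,0.8,7.9,77.2,0.002
grain,noodles,1.00,1.5,11.0,73.5,0.003
meat,chicken_breast,1.00,5.0,19.4,2.5,0.063
meat,pork_belly,1.00,37.0,13.6,2.2,0.059
meat,beef_brisket,1.00,8.0,20.0,1.2,0.057
fish,grass_carp,0.58,5.2,16.6,0.5,0.046
egg,egg,0.88,8.8,13.3,2.8,0.131
vegetable,pakchoi,0.92,0.3,1.5,2.7,0.055
vegetable,potato,0.94,0.2,2.0,17.8,0.003
", stringsAsFactors = FALSE)
  for (nut in MACRONUTRIENTS)
    df[[paste0(nut, "_sd")]] <- pmax(0.1 * df[[paste0(nut, "_mean")]], 1e-4)
  df
}

#' Specify a synthetic data set
#'
#' Bundles the parameters of the synthetic generators: per-subclass
#' composition means/SDs, number of composition records per subclass,
#' number of paired dishes per (category, method) key, the true
#' multiplicative bias between calculated and detected values, the
#' relative noise SD, and a mandatory seed.
#'
#' The generated data emulate the calibration design: composition records
#' are independent truncated-normal draws around the subclass targets, and
#' detected dish values are `calculated / bias x (1 + noise)`, so the
#' calculated/detected ratio concentrates around `bias` and the
#' recoverable correction factor around `1 / bias`.
#'
#' @param subclasses targets table, see [synthetic_subclass_targets()].
#' @param n_per_subclass composition records drawn per subclass.
#' @param n_dishes paired dishes per (category, method) key.
#' @param bias true calculated/detected bias (scalar, or named per
#'   nutrient).
#' @param noise_sd relative SD of the multiplicative detection noise.
#' @param seed integer seed (mandatory).
#' @return list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(subclasses = synthetic_subclass_targets(),
                           n_per_subclass = 200, n_dishes = 20,
                           bias = 3, noise_sd = 0.05, seed) {
  if (missing(seed) || !is.finite(seed))
    stop_dishlabel("validation_error", "a seed is mandatory")
  if (noise_sd < 0 || n_per_subclass < 1 || n_dishes < 1)
    stop_dishlabel("validation_error", "invalid synthetic spec")
  if (is.null(names(bias)))
    bias <- setNames(rep_len(bias, 4), MACRONUTRIENTS)
  if (any(bias <= 0))
    stop_dishlabel("validation_error", "bias factors must be > 0")
  structure(list(subclasses = subclasses,
                 n_per_subclass = as.integer(n_per_subclass),
                 n_dishes = as.integer(n_dishes),
                 bias = bias, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic composition table
#'
#' Draws `n_per_subclass` ingredient records per subclass with each
#' nutrient independent normal around the subclass target mean, truncated
#' at 0. Water and ash are left absent: with them drawn independently the
#' proximate-sum invariant real tables satisfy would not hold. Same seed,
#' same output.
#'
#' @param spec a [synthetic_spec()].
#' @return a `"composition_records"` data.frame.
#' @export
generate_synthetic_composition <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    sub <- spec$subclasses
    n <- spec$n_per_subclass
    rows <- lapply(seq_len(nrow(sub)), function(i) {
      out <- data.frame(
        id = sprintf("%s_%03d", sub$subclass[i], seq_len(n)),
        name = sprintf("%s variety %03d", sub$subclass[i], seq_len(n)),
        general_category = sub$general_category[i],
        subclass = sub$subclass[i],
        edible_fraction = sub$edible_fraction[i],
        stringsAsFactors = FALSE)
      for (nut in MACRONUTRIENTS)
        out[[nut]] <- pmax(0, rnorm(n, sub[[paste0(nut, "_mean")]][i],
                                    sub[[paste0(nut, "_sd")]][i]))
      out$water <- NA_real_
      out$ash <- NA_real_
      out
    })
    res <- do.call(rbind, rows)
    class(res) <- c("composition_records", "data.frame")
    res
  })
}

#' Generate synthetic paired calculated/detected observations
#'
#' For each (category, method) key draws `n_dishes` dishes with positive
#' calculated values, then sets
#' `detected = calculated / bias x (1 + noise)`, noise ~ N(0, noise_sd),
#' truncated at 0. With `bias = 1` and `noise_sd = 0` detected equals
#' calculated exactly.
#'
#' @param spec a [synthetic_spec()].
#' @param keys data.frame of `category, method` keys; default one
#'   stir-fried synthetic category.
#' @return a [paired_observations()] data.frame.
#' @export
generate_synthetic_pairs <- function(spec,
                                     keys = data.frame(
                                       category = "synthetic",
                                       method = "stir_frying",
                                       stringsAsFactors = FALSE)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 1L, {
    rows <- lapply(seq_len(nrow(keys)), function(k) {
      calc <- data.frame(
        dish_name = sprintf("%s_%s_dish_%03d", keys$category[k],
                            keys$method[k], seq_len(spec$n_dishes)),
        category = keys$category[k], method = keys$method[k],
        stringsAsFactors = FALSE)
      det <- calc
      for (nut in MACRONUTRIENTS) {
        base <- if (nut == "sodium") runif(spec$n_dishes, 0.1, 1)
                else runif(spec$n_dishes, 5, 40)
        calc[[nut]] <- base
        det[[nut]] <- pmax(0, base / spec$bias[[nut]] *
                             (1 + rnorm(spec$n_dishes, 0, spec$noise_sd)))
      }
      list(calc = calc, det = det)
    })
    calc <- do.call(rbind, lapply(rows, `[[`, "calc"))
    det <- do.call(rbind, lapply(rows, `[[`, "det"))
    paired_observations(calc, det, by = "position")
  })
}

#' Generate a full synthetic data set
#'
#' Runs both generators and optionally writes the results as CSV.
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional output directory; when given, writes
#'   `synthetic_composition.csv`, `synthetic_calculated.csv` and
#'   `synthetic_detected.csv`.
#' @return list with `composition` and `pairs`.
#' @export
generate_synthetic <- function(spec, dir = NULL) {
  comp <- generate_synthetic_composition(spec)
  pairs <- generate_synthetic_pairs(spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out <- comp
    for (nut in PROXIMATES) {
      out[[paste0(nut, "_g")]] <- out[[nut]]
      out[[nut]] <- NULL
    }
    write.csv(out, file.path(dir, "synthetic_composition.csv"),
              row.names = FALSE, quote = TRUE)
    calc <- pairs[c("dish_name", "category", "method")]
    det <- calc
    for (nut in MACRONUTRIENTS) {
      calc[[nut]] <- pairs[[paste0("calc_", nut)]]
      det[[nut]] <- pairs[[paste0("det_", nut)]]
    }
    write.csv(calc, file.path(dir, "synthetic_calculated.csv"),
              row.names = FALSE, quote = TRUE)
    write.csv(det, file.path(dir, "synthetic_detected.csv"),
              row.names = FALSE, quote = TRUE)
  }
  list(composition = comp, pairs = pairs)
}
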