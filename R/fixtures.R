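fixture_path <- function(name) {
  system.file("extdata", name, package = "dishlabel", mustWork = TRUE)
}

#' Load the packaged measurement tables
#'
#' The package ships five plain-CSV tables transcribed from the study that
#' calibrated the model: the sampling plan (15 ingredient rows), the
#' raw-to-cooked ratio table (44 dishes), the laboratory-detected
#' macronutrient table (48 dishes, mean and SD per nutrient), the
#' model-calculated macronutrient table (48 dishes) and the printed
#' calculated/detected ratio table with its star flags (48 dishes). The
#' detected and calculated tables are aligned row by row; the SD columns
#' are carried but unused by computation.
#'
#' @return list of class `"fixture_bundle"` with elements `ratio_table`,
#'   `detected`, `calculated`, `printed_ratios`, `sampling_plan`.
#' @export
load_fixtures <- function() {
  b <- list(
    ratio_table = load_ratio_table(),
    detected = read.csv(fixture_path("detected_nutrients.csv"),
                        stringsAsFactors = FALSE, encoding = "UTF-8"),
    calculated = read.csv(fixture_path("calculated_nutrients.csv"),
                          stringsAsFactors = FALSE, encoding = "UTF-8"),
    printed_ratios = read.csv(fixture_path("printed_ratios.csv"),
                              stringsAsFactors = FALSE, encoding = "UTF-8"),
    sampling_plan = read.csv(fixture_path("sampling_plan.csv"),
                             stringsAsFactors = FALSE, encoding = "UTF-8")
  )
  expected <- c(ratio_table = 44L, detected = 48L, calculated = 48L,
                printed_ratios = 48L, sampling_plan = 15L)
  for (nm in names(expected))
    if (nrow(b[[nm]]) != expected[[nm]])
      stop_dishlabel("integrity_error", sprintf(
        "packaged table %s has %d rows, expected %d",
        nm, nrow(b[[nm]]), expected[[nm]]))
  class(b) <- "fixture_bundle"
  b
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("Packaged tables:\n")
  for (nm in setdiff(names(x), "class"))
    cat(sprintf("  %-15s %3d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Paired observations from the packaged tables
#'
#' Pairs the packaged calculated and detected tables by row position (dish
#' and method labels drift between the two, so name matching is not
#' attempted; category and method are taken from the calculated table).
#'
#' @param bundle a [load_fixtures()] bundle.
#' @return a [paired_observations()] data.frame of 48 dishes.
#' @export
fixture_pairs <- function(bundle = load_fixtures()) {
  paired_observations(bundle$calculated, bundle$detected, by = "position")
}

#' Agreement with the printed ratio table
#'
#' Recomputes the calculated/detected ratio table from the packaged
#' calculated and detected tables and compares every cell with the printed
#' ratio table: the half-up-rounded value against the printed value
#' (within `tol`) and the recomputed screening flag against the printed
#' star.
#'
#' @param bundle a [load_fixtures()] bundle.
#' @param tol absolute tolerance on the rounded ratio, default 0.01.
#' @return data.frame of class `"printed_agreement"` with one row per cell
#'   (`dish_name, nutrient, computed, printed, value_match, computed_flag,
#'   printed_flag, flag_match`); attributes `value_match_rate` and
#'   `flag_match_rate` give the two proportions.
#' @export
printed_ratio_agreement <- function(bundle = load_fixtures(), tol = 0.01) {
  rt <- ratio_table(fixture_pairs(bundle))
  printed <- bundle$printed_ratios
  rows <- lapply(MACRONUTRIENTS, function(nut) {
    cells <- rt[rt$nutrient == nut, ]
    data.frame(.row = seq_len(nrow(printed)),
               dish_name = printed$dish_name, nutrient = nut,
               computed = cells$value, printed = printed[[nut]],
               computed_flag = cells$flagged,
               printed_flag = printed[[paste0(nut, "_flag")]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$.row, match(out$nutrient, MACRONUTRIENTS)), ]
  out$.row <- NULL
  rownames(out) <- NULL
  out$value_match <- !is.na(out$computed) &
    abs(out$computed - out$printed) <= tol + 1e-9
  out$flag_match <- out$computed_flag == out$printed_flag
  attr(out, "value_match_rate") <- mean(out$value_match)
  attr(out, "flag_match_rate") <- mean(out$flag_match)
  class(out) <- c("printed_agreement", "data.frame")
  out
}

#' @export
print.printed_agreement <- function(x, ...) {
  cat(sprintf(
    "Printed-ratio agreement over %d cells: values %.1f%%, flags %.1f%%\n",
    nrow(x), 100 * attr(x, "value_match_rate"),
    100 * attr(x, "flag_match_rate")))
  bad <- x[!x$value_match | !x$flag_match, ]
  if (nrow(bad)) {
    cat("Disagreeing cells:\n")
    print(as.data.frame(bad), row.names = FALSE)
  }
  invisible(x)
}

#' Export the packaged tables
#'
#' Writes the five packaged CSV tables into a directory.
#'
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
export_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c("raw_cooked_ratios.csv", "detected_nutrients.csv",
             "calculated_nutrients.csv", "printed_ratios.csv",
             "sampling_plan.csv")
  out <- vapply(files, function(f) {
    dest <- file.path(dir, f)
    file.copy(fixture_path(f), dest, overwrite = TRUE)
    dest
  }, character(1))
  invisible(out)
}
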