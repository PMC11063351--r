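#' Pair calculated and detected nutrient tables
#'
#' Aligns a model-calculated and a laboratory-detected wide table (columns
#' `category,dish_name,method,fat,protein,sodium,carbohydrate`, values in
#' g/100 g cooked) into one paired table. Alignment is by dish name
#' (default) or by row position; position alignment is what the packaged
#' tables need, since dish and method labels drift between them. The
#' `category` and `method` carried forward come from the calculated table.
#'
#' @param calculated,detected wide data.frames as above.
#' @param by `"dish_name"` or `"position"`.
#' @return data.frame of class `"paired_observations"` with columns
#'   `dish_name,category,method` and `calc_*` / `det_*` per nutrient.
#' @export
paired_observations <- function(calculated, detected,
                                by = c("dish_name", "position")) {
  by <- match.arg(by)
  for (tab in list(calculated, detected)) {
    missing <- setdiff(c("dish_name", MACRONUTRIENTS), names(tab))
    if (length(missing))
      stop_dishlabel("schema_error", "paired table missing column(s): ",
                     paste(missing, collapse = ", "))
  }
  if (by == "dish_name") {
    if (anyDuplicated(calculated$dish_name) ||
        anyDuplicated(detected$dish_name))
      stop_dishlabel("alignment_error",
                     "duplicate dish names; use by = \"position\"")
    orphans <- c(setdiff(calculated$dish_name, detected$dish_name),
                 setdiff(detected$dish_name, calculated$dish_name))
    if (length(orphans))
      stop_dishlabel("alignment_error",
                     "dishes present in only one table: ",
                     paste(unique(orphans), collapse = ", "))
    detected <- detected[match(calculated$dish_name, detected$dish_name), ]
  } else if (nrow(calculated) != nrow(detected)) {
    stop_dishlabel("alignment_error", sprintf(
      "position alignment needs equal row counts (%d vs %d)",
      nrow(calculated), nrow(detected)))
  }
  if (any(detected[MACRONUTRIENTS] < 0, na.rm = TRUE))
    stop_dishlabel("validation_error", "detected values must be >= 0")
  out <- data.frame(
    dish_name = calculated$dish_name,
    category = calculated$category %||% NA_character_,
    method = normalize_method(calculated$method),
    stringsAsFactors = FALSE
  )
  for (nut in MACRONUTRIENTS) {
    out[[paste0("calc_", nut)]] <- as.numeric(calculated[[nut]])
    out[[paste0("det_", nut)]] <- as.numeric(detected[[nut]])
  }
  class(out) <- c("paired_observations", "data.frame")
  out
}

#' Screen a calculated/detected ratio
#'
#' A cell is flagged for correction when the calculated-to-detected ratio
#' is at or beyond the screening bounds — at most `low` (default 0.5) or at
#' least `high` (default 2), bounds inclusive — or undefined (`NA`,
#' detected 0 with calculated > 0).
#'
#' @param ratio numeric vector of ratios (>= 0 or `NA`).
#' @param low,high inclusive screening bounds.
#' @return logical vector.
#' @export
#' @examples
#' screen(c(0.55, 2.17, 0.5, NA)) # FALSE TRUE TRUE TRUE
screen <- function(ratio, low = 0.5, high = 2) {
  is.na(ratio) | ratio <= low | ratio >= high
}

#' Calculated/detected ratio table
#'
#' Per dish and nutrient: ratio = calculated / detected. The reported value
#' is rounded half-up to `round_dp` decimals, but the screening flag is
#' computed on the unrounded ratio (a printed "0.50" may be flagged or not
#' depending on its unrounded value). Degenerate cells: calculated 0 gives
#' ratio 0 (flagged); detected 0 with calculated > 0 gives an undefined
#' ratio, flagged and reported as `NA` with `defined = FALSE`.
#'
#' @param pairs a [paired_observations()] data.frame.
#' @param round_dp decimals for the displayed ratio.
#' @param low,high screening bounds, see [screen()].
#' @return long data.frame of class `"ratio_cells"`: `dish_name, category,
#'   method, nutrient, calculated, detected, ratio` (unrounded), `value`
#'   (rounded), `display` (string, `"*"`-suffixed when flagged), `flagged`,
#'   `defined`.
#' @export
ratio_table <- function(pairs, round_dp = 2, low = 0.5, high = 2) {
  stopifnot(inherits(pairs, "paired_observations"))
  rows <- lapply(MACRONUTRIENTS, function(nut) {
    calc <- pairs[[paste0("calc_", nut)]]
    det <- pairs[[paste0("det_", nut)]]
    ratio <- ifelse(calc == 0, 0, ifelse(det == 0, NA_real_, calc / det))
    defined <- !(calc > 0 & det == 0)
    data.frame(.row = seq_len(nrow(pairs)),
               dish_name = pairs$dish_name, category = pairs$category,
               method = pairs$method, nutrient = nut,
               calculated = calc, detected = det,
               ratio = ratio, defined = defined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$.row, match(out$nutrient, MACRONUTRIENTS)), ]
  out$.row <- NULL
  rownames(out) <- NULL
  out$flagged <- screen(out$ratio, low, high)
  out$value <- round_half_up(out$ratio, round_dp)
  out$display <- ifelse(is.na(out$ratio), "undef",
                        formatC(out$value, format = "f", digits = round_dp))
  out$display <- paste0(out$display, ifelse(out$flagged, "*", ""))
  attr(out, "thresholds") <- c(low = low, high = high)
  class(out) <- c("ratio_cells", "data.frame")
  out
}

#' Fit cooking-method correction factors
#'
#' Derives multiplicative correction factors from paired
#' calculated/detected observations, pooled per (category, method,
#' nutrient) key. A key whose supporting cells include at least one flagged
#' ratio (see [screen()]) gets an active factor equal to the `aggregate` of
#' detected/calculated over its defined cells (cells with calculated 0 are
#' excluded from aggregation); all other keys keep factor 1 and stay
#' inactive. A flagged key with no defined cells yields a
#' factor-underivable warning and factor 1.
#'
#' Applying an active factor multiplies the model-calculated value so that,
#' on the training data, corrected values move toward the detected values;
#' a singleton-support factor reproduces its detected value exactly.
#'
#' @param pairs a [paired_observations()] data.frame.
#' @param low,high screening bounds, see [screen()].
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return an object of class `"correction_model"` with elements `factors`
#'   (data.frame `category,method,nutrient,factor,n_support,active`),
#'   `thresholds`, `aggregate` and the training `ratio_table`.
#' @seealso [predict.correction_model()], [validate_correction()]
#' @export
correction_model <- function(pairs, low = 0.5, high = 2,
                             aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  rt <- ratio_table(pairs, low = low, high = high)
  agg_fun <- if (aggregate == "mean") mean else median
  key <- paste(rt$category, rt$method, rt$nutrient, sep = "\r")
  groups <- split(seq_len(nrow(rt)), key)
  rows <- lapply(groups, function(idx) {
    g <- rt[idx, ]
    out <- data.frame(category = g$category[1], method = g$method[1],
                      nutrient = g$nutrient[1], factor = 1,
                      n_support = 0L, active = FALSE,
                      stringsAsFactors = FALSE)
    if (any(g$flagged)) {
      usable <- g$calculated > 0 & g$detected >= 0
      f <- if (any(usable))
        agg_fun(g$detected[usable] / g$calculated[usable]) else 0
      if (f <= 0) {
        warning(sprintf(
          "factor underivable for (%s, %s, %s): no usable cells",
          out$category, out$method, out$nutrient), call. = FALSE)
      } else {
        out$factor <- f
        out$n_support <- sum(usable)
        out$active <- TRUE
      }
    }
    out
  })
  factors <- do.call(rbind, rows)
  factors <- factors[order(factors$category, factors$method,
                           match(factors$nutrient, MACRONUTRIENTS)), ]
  rownames(factors) <- NULL
  structure(list(factors = factors, thresholds = c(low = low, high = high),
                 aggregate = aggregate, ratio_table = rt,
                 call = match.call()),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  f <- x$factors
  cat(sprintf(paste0("Cooking-method correction model: %d (category, method,",
                     " nutrient) keys, %d active\n"), nrow(f), sum(f$active)))
  cat(sprintf("Screening bounds: ratio <= %s or >= %s (on unrounded ratios); ",
              format(x$thresholds[["low"]]), format(x$thresholds[["high"]])))
  cat(sprintf("aggregation: %s of detected/calculated\n", x$aggregate))
  invisible(x)
}

#' @export
coef.correction_model <- function(object, active_only = FALSE, ...) {
  f <- object$factors
  if (active_only) f <- f[f$active, ]
  setNames(f$factor, paste(f$category, f$method, f$nutrient, sep = ":"))
}

#' @export
summary.correction_model <- function(object, ...) {
  f <- object$factors
  per_nut <- do.call(rbind, lapply(MACRONUTRIENTS, function(nut) {
    g <- f[f$nutrient == nut, ]
    a <- g[g$active, ]
    data.frame(nutrient = nut, n_keys = nrow(g), n_active = nrow(a),
               min_factor = if (nrow(a)) min(a$factor) else NA_real_,
               max_factor = if (nrow(a)) max(a$factor) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(model = object, per_nutrient = per_nut,
                 active = f[f$active, ]),
            class = "summary.correction_model")
}

#' @export
print.summary.correction_model <- function(x, ...) {
  print(x$model)
  cat("\nPer-nutrient key counts and active factor range:\n")
  print(x$per_nutrient, row.names = FALSE)
  invisible(x)
}

# Find the factor for a (category/subclass, method, nutrient) key; 1 when
# absent. Accepts a correction_model or a bare factors data.frame.
lookup_factor <- function(corrections, category, subclass = NULL, method,
                          nutrient) {
  f <- if (inherits(corrections, "correction_model")) corrections$factors
       else corrections
  method <- normalize_method(method)
  keys <- tolower(c(subclass %||% character(0), category %||% character(0)))
  for (k in keys) {
    idx <- which(tolower(f$category) == k &
                 normalize_method(f$method) == method &
                 f$nutrient == nutrient)
    if (length(idx)) return(f$factor[idx[1]])
  }
  1
}

#' Apply a correction model to calculated values
#'
#' Multiplies each calculated value by its key's factor. For
#' `"paired_observations"` input the result is the long [ratio_table()]
#' layout with `factor` and `corrected` columns appended; a long
#' data.frame with `category, method, nutrient, calculated` columns is also
#' accepted.
#'
#' @param object a `"correction_model"`.
#' @param newdata paired observations or a long data.frame; defaults to the
#'   training pairs' cells.
#' @param ... unused.
#' @return data.frame with `factor` and `corrected` columns.
#' @export
predict.correction_model <- function(object, newdata = NULL, ...) {
  cells <- if (is.null(newdata)) object$ratio_table
    else if (inherits(newdata, "paired_observations")) ratio_table(
      newdata, low = object$thresholds[["low"]],
      high = object$thresholds[["high"]])
    else newdata
  need <- c("category", "method", "nutrient", "calculated")
  missing <- setdiff(need, names(cells))
  if (length(missing))
    stop_dishlabel("schema_error", "newdata missing column(s): ",
                   paste(missing, collapse = ", "))
  cells$factor <- vapply(seq_len(nrow(cells)), function(i)
    lookup_factor(object, category = cells$category[i],
                  method = cells$method[i], nutrient = cells$nutrient[i]),
    numeric(1))
  cells$corrected <- cells$calculated * cells$factor
  cells
}

#' @export
residuals.correction_model <- function(object, ...) {
  p <- predict(object)
  p$detected - p$corrected
}

#' Before/after validation of a correction model
#'
#' Compares model-calculated against detected values before and after
#' applying the correction factors: mean absolute error (MAE, g/100 g) and
#' mean absolute percentage error (MAPE, % of the detected value, over
#' cells with detected > 0), per nutrient and overall. Any nutrient whose
#' error increased after correction is flagged in the report.
#'
#' @param pairs a [paired_observations()] data.frame.
#' @param model a `"correction_model"` (typically fit on the same key
#'   space).
#' @return an object of class `"correction_validation"` with a `table`
#'   data.frame (`nutrient, mae_before, mae_after, mape_before, mape_after,
#'   error_increased`) whose last row is the overall summary.
#' @export
validate_correction <- function(pairs, model) {
  p <- predict(model, newdata = pairs)
  summarize <- function(g, label) {
    pos <- g$detected > 0
    data.frame(
      nutrient = label,
      mae_before = mean(abs(g$calculated - g$detected)),
      mae_after = mean(abs(g$corrected - g$detected)),
      mape_before = if (any(pos))
        100 * mean(abs(g$calculated[pos] - g$detected[pos]) / g$detected[pos])
        else NA_real_,
      mape_after = if (any(pos))
        100 * mean(abs(g$corrected[pos] - g$detected[pos]) / g$detected[pos])
        else NA_real_,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(MACRONUTRIENTS, function(nut)
    summarize(p[p$nutrient == nut, ], nut)))
  tab <- rbind(tab, summarize(p, "overall"))
  tab$error_increased <- tab$mae_after > tab$mae_before
  structure(list(table = tab, n_cells = nrow(p)),
            class = "correction_validation")
}

#' @export
print.correction_validation <- function(x, ...) {
  cat(sprintf("Correction validation over %d cells (MAE g/100 g, MAPE %%):\n",
              x$n_cells))
  tab <- x$table
  for (col in c("mae_before", "mae_after", "mape_before", "mape_after"))
    tab[[col]] <- round_half_up(tab[[col]], 2)
  print(tab, row.names = FALSE)
  inc <- x$table$nutrient[x$table$error_increased &
                          x$table$nutrient != "overall"]
  if (length(inc))
    cat("Warning: error increased after correction for:",
        paste(inc, collapse = ", "), "\n")
  invisible(x)
}

#' Read/write correction factors as CSV
#'
#' @param factors a `"correction_model"` or its factors data.frame.
#' @param path CSV path (`category,method,nutrient,factor,n_support,active`).
#' @return `path` invisibly (write); a factors data.frame (read).
#' @export
write_correction_factors <- function(factors, path) {
  if (inherits(factors, "correction_model")) factors <- factors$factors
  write.csv(factors, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_correction_factors
#' @export
read_correction_factors <- function(path) {
  f <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("category", "method", "nutrient", "factor")
  missing <- setdiff(need, names(f))
  if (length(missing))
    stop_dishlabel("schema_error", "factor table missing column(s): ",
                   paste(missing, collapse = ", "))
  if (any(f$factor <= 0))
    stop_dishlabel("validation_error", "correction factors must be > 0")
  f
}
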