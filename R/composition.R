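#' Read a raw-material composition table
#'
#' Loads a food composition table (FCT) of per-100 g edible-portion nutrient
#' values for raw ingredients. The CSV must carry the columns
#' `id,name,general_category,subclass,edible_fraction,water_g,protein_g,
#' fat_g,carbohydrate_g,ash_g` and exactly one sodium column: `sodium_g`
#' or `sodium_mg` (the latter is converted to g/100 g on load).
#'
#' Rows failing the record invariants (duplicate id, empty subclass,
#' edible fraction outside (0, 1], negative nutrient) are rejected with a
#' row-addressed diagnostic.
#'
#' @param source path to a UTF-8 CSV file, or a data.frame already in the
#'   same layout.
#' @return a data.frame of class `"composition_records"` with normalized
#'   columns `id,name,general_category,subclass,edible_fraction,
#'   fat,protein,carbohydrate,sodium,water,ash` (all nutrients g/100 g).
#' @seealso [representative_values()], [composition_db()]
#' @export
read_composition_table <- function(source) {
  df <- if (is.data.frame(source)) source else {
    if (!file.exists(source))
      stop_dishlabel("schema_error", "composition table not found: ", source)
    read.csv(source, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
  required <- c("id", "name", "general_category", "subclass",
                "edible_fraction", "water_g", "protein_g", "fat_g",
                "carbohydrate_g", "ash_g")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_dishlabel("schema_error", "missing required column(s): ",
                   paste(missing, collapse = ", "))
  has_g <- "sodium_g" %in% names(df)
  has_mg <- "sodium_mg" %in% names(df)
  if (has_g && has_mg)
    stop_dishlabel("schema_error",
                   "exactly one of sodium_g / sodium_mg is allowed, found both")
  if (!has_g && !has_mg)
    stop_dishlabel("schema_error", "missing sodium column (sodium_g or sodium_mg)")
  sodium <- if (has_g) as.numeric(df$sodium_g) else as.numeric(df$sodium_mg) / 1000

  out <- data.frame(
    id = as.character(df$id),
    name = as.character(df$name),
    general_category = as.character(df$general_category),
    subclass = as.character(df$subclass),
    edible_fraction = as.numeric(df$edible_fraction),
    fat = as.numeric(df$fat_g),
    protein = as.numeric(df$protein_g),
    carbohydrate = as.numeric(df$carbohydrate_g),
    sodium = sodium,
    water = as.numeric(df$water_g),
    ash = as.numeric(df$ash_g),
    stringsAsFactors = FALSE
  )
  validate_composition_records(out)
  class(out) <- c("composition_records", "data.frame")
  out
}

validate_composition_records <- function(out) {
  dup <- out$id[duplicated(out$id)]
  if (length(dup))
    stop_dishlabel("uniqueness_error", "duplicate ingredient id(s): ",
                   paste(unique(dup), collapse = ", "))
  for (i in seq_len(nrow(out))) {
    row <- out[i, ]
    if (is.na(row$subclass) || !nzchar(row$subclass))
      stop_dishlabel("validation_error", sprintf("row %d: empty subclass", i))
    ef <- row$edible_fraction
    if (is.na(ef) || ef <= 0 || ef > 1)
      stop_dishlabel("validation_error", sprintf(
        "row %d (%s): edible_fraction %s outside (0, 1]", i, row$id, format(ef)))
    for (nut in PROXIMATES) {
      v <- row[[nut]]
      if (!is.na(v) && v < 0)
        stop_dishlabel("validation_error", sprintf(
          "row %d (%s): negative %s (%s)", i, row$id, nut, format(v)))
    }
    if (!is.na(row$water) && !is.na(row$ash)) {
      s <- sum(row$fat, row$protein, row$carbohydrate, row$water, row$ash,
               na.rm = TRUE)
      if (s > 100.5)
        stop_dishlabel("validation_error", sprintf(
          "row %d (%s): proximate sum %.2f g exceeds 100.5 g", i, row$id, s))
    }
  }
  invisible(out)
}

#' Representative nutrient values per food group
#'
#' Collapses composition records into one representative value per group:
#' the unweighted arithmetic mean of each nutrient over group members.
#' Members missing an optional nutrient are skipped for that nutrient (no
#' imputation) and the per-nutrient member count is reported.
#'
#' Representative values stand in for ingredient varieties absent from the
#' composition table: an unknown variety of a known subclass is assigned the
#' subclass representative (see [resolve_ingredient()]).
#'
#' @param records a `"composition_records"` data.frame.
#' @param level grouping tier: `"subclass"` (default; groups by
#'   general_category x subclass) or `"general_category"`.
#' @return a data.frame of class `"representative_values"`: grouping
#'   columns, mean nutrient columns, `n_members`, and per-nutrient counts
#'   `n_fat`, ..., `n_ash`.
#' @export
representative_values <- function(records,
                                  level = c("subclass", "general_category")) {
  level <- match.arg(level)
  if (!is.data.frame(records) || nrow(records) == 0)
    stop_dishlabel("validation_error", "records must be a non-empty data.frame")
  keycols <- if (level == "subclass") c("general_category", "subclass")
             else "general_category"
  if (any(is.na(records[keycols]) | records[keycols] == ""))
    stop_dishlabel("validation_error",
                   "every record must carry the grouping label ",
                   paste(keycols, collapse = "+"))
  key <- do.call(paste, c(records[keycols], sep = "\r"))
  groups <- split(seq_len(nrow(records)), key)
  rows <- lapply(groups, function(idx) {
    g <- records[idx, , drop = FALSE]
    out <- g[1, keycols, drop = FALSE]
    for (nut in PROXIMATES) {
      v <- g[[nut]]
      ok <- !is.na(v)
      out[[nut]] <- if (any(ok)) sum(v[ok]) / sum(ok) else NA_real_
      out[[paste0("n_", nut)]] <- sum(ok)
    }
    out$n_members <- nrow(g)
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(do.call(paste, res[keycols])), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "level") <- level
  class(res) <- c("representative_values", "data.frame")
  res
}

#' Build a composition database
#'
#' Bundles composition records with precomputed subclass and
#' general-category representative values for fallback ingredient
#' resolution.
#'
#' @param records a `"composition_records"` data.frame (or anything
#'   [read_composition_table()] accepts).
#' @return a list of class `"composition_db"` with elements `records`,
#'   `subclass` and `general_category` representative tables.
#' @export
composition_db <- function(records) {
  if (!inherits(records, "composition_records"))
    records <- read_composition_table(records)
  structure(list(
    records = records,
    subclass = representative_values(records, "subclass"),
    general_category = representative_values(records, "general_category")
  ), class = "composition_db")
}

#' @export
print.composition_db <- function(x, ...) {
  cat(sprintf("Composition database: %d records, %d subclasses, %d categories\n",
              nrow(x$records), nrow(x$subclass), nrow(x$general_category)))
  invisible(x)
}

#' Resolve an ingredient to per-100 g nutrients
#'
#' Resolution never fabricates values; it returns, in order of preference:
#' the matching record's own nutrients (tag `"exact"`, matched on name or
#' id), the declared subclass's representative values (tag `"subclass"`),
#' or the declared general category's representative values (tag
#' `"category"`). With no match at any level an unresolvable-ingredient
#' error lists the known subclasses.
#'
#' @param query_name ingredient name or id.
#' @param db a `"composition_db"`.
#' @param subclass,general_category optional declared classification of the
#'   queried ingredient, used for fallback when the name is unknown.
#' @return a list of class `"ingredient_resolution"`: `nutrients`
#'   (a [nutrient_vector()]), `level` tag, `general_category`, `subclass`,
#'   and `edible_fraction` (`NA` unless resolved exactly).
#' @export
resolve_ingredient <- function(query_name, db, subclass = NULL,
                               general_category = NULL) {
  stopifnot(inherits(db, "composition_db"))
  if (!is_string(query_name))
    stop_dishlabel("validation_error", "query_name must be a single string")
  rec <- db$records
  hit <- which(rec$name == query_name | rec$id == query_name)
  if (length(hit)) {
    r <- rec[hit[1], ]
    return(structure(list(
      nutrients = as_nutrient_vector(
        as.list(r[PROXIMATES])),
      level = "exact",
      general_category = r$general_category,
      subclass = r$subclass,
      edible_fraction = r$edible_fraction
    ), class = "ingredient_resolution"))
  }
  if (!is.null(subclass)) {
    reps <- db$subclass
    hit <- which(tolower(reps$subclass) == tolower(subclass))
    if (length(hit)) {
      r <- reps[hit[1], ]
      return(structure(list(
        nutrients = as_nutrient_vector(as.list(r[PROXIMATES])),
        level = "subclass",
        general_category = r$general_category,
        subclass = r$subclass,
        edible_fraction = NA_real_
      ), class = "ingredient_resolution"))
    }
  }
  if (!is.null(general_category)) {
    reps <- db$general_category
    hit <- which(tolower(reps$general_category) == tolower(general_category))
    if (length(hit)) {
      r <- reps[hit[1], ]
      return(structure(list(
        nutrients = as_nutrient_vector(as.list(r[PROXIMATES])),
        level = "category",
        general_category = r$general_category,
        subclass = NA_character_,
        edible_fraction = NA_real_
      ), class = "ingredient_resolution"))
    }
  }
  stop_dishlabel("unresolvable_ingredient_error", sprintf(
    "cannot resolve '%s' at any level; known subclasses: %s", query_name,
    paste(sort(unique(rec$subclass)), collapse = ", ")))
}

#' Export representative values as CSV
#'
#' Writes a representative-value table back in the composition-table CSV
#' dialect (`*_g` nutrient columns) with `n_members` appended.
#'
#' @param reps a `"representative_values"` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_representatives <- function(reps, path) {
  stopifnot(inherits(reps, "representative_values"))
  out <- reps[intersect(c("general_category", "subclass"), names(reps))]
  for (nut in PROXIMATES) out[[paste0(nut, "_g")]] <- reps[[nut]]
  out$n_members <- reps$n_members
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
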