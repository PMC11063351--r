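# Small in-code fixtures shared across tests.

small_composition_csv <- function(path = tempfile(fileext = ".csv"),
                                  sodium_col = "sodium_g") {
  rows <- c(
    "id,name,general_category,subclass,edible_fraction,water_g,protein_g,fat_g,carbohydrate_g,ash_g,SOD",
    "rice_01,rice (polished),grain,rice,1,13.3,7.9,0.8,77.2,0.6,0.002",
    "rice_02,rice (northeast),grain,rice,1,12.9,7.3,1.0,77.7,0.5,0.004",
    "egg_01,hen egg,egg,egg,0.88,74.1,13.3,8.8,2.8,1.0,0.131",
    "pot_01,potato,vegetable,potato,0.94,78.6,2.0,0.2,17.8,1.0,0.003",
    "pak_01,pakchoi,vegetable,pakchoi,0.92,94.5,1.5,0.3,2.7,0.8,0.055"
  )
  rows[1] <- sub("SOD", sodium_col, rows[1])
  if (sodium_col == "sodium_mg") {
    # same sodium contents expressed in mg/100 g
    rows[-1] <- vapply(rows[-1], function(r) {
      parts <- strsplit(r, ",")[[1]]
      parts[11] <- format(as.numeric(parts[11]) * 1000)
      paste(parts, collapse = ",")
    }, character(1), USE.NAMES = FALSE)
  }
  writeLines(rows, path)
  path
}

small_db <- function() composition_db(read_composition_table(small_composition_csv()))

# A tiny ratio table independent of the packaged one.
toy_ratios <- function() {
  as_ratio_table(data.frame(
    category = c("grain", "vegetable"),
    subclass = c("rice", "potato"),
    dish_name = c("steamed rice", "boiled potato"),
    method = c("Steaming", "Boiling"),
    ratio = c(0.5, 1.25),
    stringsAsFactors = FALSE))
}

# Random single-category paired tables with an exact multiplicative bias.
biased_pairs <- function(n = 20, bias = 3, noise_sd = 0.05, seed = 11,
                         category = "synthetic", method = "stir_frying") {
  spec <- synthetic_spec(n_dishes = n, bias = bias, noise_sd = noise_sd,
                         seed = seed)
  generate_synthetic_pairs(spec, keys = data.frame(
    category = category, method = method, stringsAsFactors = FALSE))
}
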