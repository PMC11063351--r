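test_that("nutrient summation over resolved lines is a mass-weighted sum", {
  lines <- data.frame(fat = c(10, 20), protein = c(0, 0),
                      carbohydrate = c(0, 0), sodium = c(0, 0),
                      edible_mass_g = c(100, 100))
  expect_equal(sum_nutrients(lines)[["fat"]], 30)

  one <- data.frame(fat = 0, protein = 20, carbohydrate = 0, sodium = 0,
                    edible_mass_g = 250)
  expect_equal(sum_nutrients(one)[["protein"]], 50)

  expect_equal(sum(sum_nutrients(lines[0, ])), 0)
})

test_that("label per-100 g values follow the mass-conservation reading", {
  db <- small_db()
  # measured cooked weight: 200 g rice -> 400 g cooked
  d <- dish("test", "steaming", data.frame(food = "rice_01", raw_mass_g = 200),
            cooked_weight_g = 400)
  lab <- compute_label(d, db, ratios = toy_ratios())
  expect_equal(lab$weight_source, "measured")
  expect_equal(lab$per_100g[["protein"]], 7.9 * 200 / 100 / 400 * 100)

  # estimated weight via ratio 0.5 gives the same dish
  d2 <- dish("test", "steaming", data.frame(food = "rice_01", raw_mass_g = 200))
  lab2 <- compute_label(d2, db, ratios = toy_ratios())
  expect_equal(lab2$weight_source, "estimated")
  expect_equal(lab2$cooked_weight_g, 400)
  # single ingredient closed form: per-100 g = raw content x ratio
  expect_equal(lab2$per_100g[["protein"]], 7.9 * 0.5)

  # correction factor scales linearly
  fac <- data.frame(category = "grain", method = "steaming",
                    nutrient = "protein", factor = 2)
  lab3 <- compute_label(d2, db, ratios = toy_ratios(), corrections = fac)
  expect_equal(lab3$per_100g[["protein"]], 7.9)
  expect_true(lab3$corrected)
  expect_equal(lab3$applied_factors$factor, 2)
})

test_that("edible fraction and its override reduce the edible mass", {
  db <- small_db()
  # potato record has edible fraction 0.94
  d <- dish("p", "boiling", data.frame(food = "pot_01", raw_mass_g = 100),
            cooked_weight_g = 100)
  lab <- compute_label(d, db, ratios = toy_ratios())
  expect_equal(lab$totals[["protein"]], 2.0 * 94 / 100)

  d2 <- dish("p", "boiling", data.frame(food = "pot_01", raw_mass_g = 100,
                                        edible_fraction = 0.5),
             cooked_weight_g = 100)
  lab2 <- compute_label(d2, db, ratios = toy_ratios())
  expect_equal(lab2$totals[["protein"]], 1.0)
})

test_that("seasonings add only fat, sodium and sugar carbohydrate", {
  db <- small_db()
  d <- dish("seasoned rice", "steaming",
            data.frame(food = "rice_01", raw_mass_g = 100),
            seasonings = data.frame(kind = c("oil", "salt", "sugar"),
                                    mass_g = c(10, 2, 5)),
            cooked_weight_g = 200)
  lab <- compute_label(d, db, ratios = toy_ratios())
  base <- compute_label(dish("plain", "steaming",
                             data.frame(food = "rice_01", raw_mass_g = 100),
                             cooked_weight_g = 200), db, ratios = toy_ratios())
  expect_equal(lab$totals[["fat"]] - base$totals[["fat"]], 10 * 0.999)
  expect_equal(lab$totals[["sodium"]] - base$totals[["sodium"]], 2 * 0.393)
  expect_equal(lab$totals[["carbohydrate"]] - base$totals[["carbohydrate"]],
               5 * 0.999)
  expect_equal(lab$totals[["protein"]], base$totals[["protein"]])

  nosugar <- compute_label(d, db, ratios = toy_ratios(),
                           sugar_carbohydrate = FALSE)
  expect_equal(nosugar$totals[["carbohydrate"]],
               base$totals[["carbohydrate"]])

  # estimated cooked weight counts seasoning mass in the raw input
  d3 <- dish("seasoned rice", "steaming",
             data.frame(food = "rice_01", raw_mass_g = 100),
             seasonings = data.frame(kind = "salt", mass_g = 10))
  lab3 <- compute_label(d3, db, ratios = toy_ratios())
  expect_equal(lab3$cooked_weight_g, 110 / 0.5)
})

test_that("label engine errors on unresolvable dishes and missing ratios", {
  db <- small_db()
  d <- dish("mystery", "steaming",
            data.frame(food = "unobtainium", raw_mass_g = 100))
  expect_error(compute_label(d, db, ratios = toy_ratios()),
               class = "unresolvable_ingredient_error")

  d2 <- dish("egg dish", "roasting",
             data.frame(food = "egg_01", raw_mass_g = 100))
  expect_error(compute_label(d2, db, ratios = toy_ratios()),
               class = "missing_ratio_error")
  expect_warning(
    lab <- compute_label(d2, db, ratios = toy_ratios(),
                         assume_unity_ratio = TRUE), "assuming 1")
  expect_equal(lab$cooked_weight_g, 88)
})

test_that("conservation and homogeneity hold for random dishes", {
  db <- small_db()
  set.seed(404)
  foods <- db$records$id
  for (i in 1:50) {
    n <- sample(1:3, 1)
    ing <- data.frame(food = sample(foods, n), raw_mass_g = runif(n, 10, 300))
    w <- runif(1, 50, 800)
    d <- dish("r", "steaming", ing, cooked_weight_g = w)
    lab <- compute_label(d, db, ratios = toy_ratios())
    # conservation: per-100 g x weight / 100 == totals
    expect_lt(max(abs(lab$per_100g * w / 100 - lab$totals)), 1e-9)
    # homogeneity: scaling all masses and the weight leaves per-100 g fixed
    k <- runif(1, 0.5, 3)
    ing2 <- ing; ing2$raw_mass_g <- ing2$raw_mass_g * k
    lab2 <- compute_label(dish("r", "steaming", ing2, cooked_weight_g = w * k),
                          db, ratios = toy_ratios())
    expect_lt(max(abs(lab2$per_100g - lab$per_100g)), 1e-9)
  }
})

test_that("energy follows the configured conversion factors", {
  expect_equal(energy_of(c(fat = 0, protein = 10, carbohydrate = 0))[["kJ"]],
               170)
  expect_equal(sum(energy_of(c(fat = 0, protein = 0, carbohydrate = 0))), 0)
  expect_equal(
    energy_of(c(protein = 10, fat = 5, carbohydrate = 20),
              factors = c(protein = 4, fat = 9, carbohydrate = 4),
              unit = "kcal")[["kcal"]], 165)
  expect_equal(energy_of(c(fat = 1, protein = 1, carbohydrate = 1))[["kcal"]],
               71 / 4.184)
  expect_error(energy_of(c(fat = -1, protein = 0, carbohydrate = 0)),
               class = "domain_error")

  # linearity
  a <- c(fat = 2, protein = 3, carbohydrate = 5)
  b <- c(fat = 1, protein = 7, carbohydrate = 0)
  expect_equal(energy_of(a + b), energy_of(a) + energy_of(b))
})

test_that("NRV percentages harmonize units before dividing", {
  p <- nrv_percent(c(fat = 0, protein = 0, carbohydrate = 0, sodium = 1))
  expect_equal(p[["sodium"]], 50)  # 1 g = 1000 mg vs 2000 mg
  expect_equal(nrv_percent(c(fat = 0, protein = 30, carbohydrate = 0,
                             sodium = 0))[["protein"]], 50)
  expect_equal(sum(nrv_percent(setNames(numeric(4),
    c("fat", "protein", "carbohydrate", "sodium")))), 0)
  expect_error(nrv_percent(c(fat = 1, protein = 1, carbohydrate = 1,
                             sodium = 0), ref = c(energy_kj = 8400,
                             protein_g = 0, fat_g = 60, carbohydrate_g = 300,
                             sodium_mg = 2000)),
               class = "config_error")

  # linearity
  a <- c(fat = 2, protein = 3, carbohydrate = 5, sodium = 0.2)
  expect_equal(nrv_percent(2 * a), 2 * nrv_percent(a))
})

test_that("recipe JSON round-trips into a dish and a printable label", {
  path <- tempfile(fileext = ".json")
  writeLines('{
    "name": "Steamed rice", "cooking_method": "Steaming",
    "ingredients": [{"food": "rice_01", "raw_mass_g": 100}],
    "seasonings": [{"kind": "salt", "mass_g": 1}]
  }', path)
  d <- read_recipe(path)
  expect_s3_class(d, "dish")
  expect_equal(d$method, "steaming")
  lab <- compute_label(d, small_db(), ratios = toy_ratios())
  out <- capture.output(print(lab))
  expect_true(any(grepl("Energy", out)))
  expect_true(any(grepl("NRV%", out)))
  json <- write_label(lab)
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$per_100g$protein, lab$per_100g[["protein"]])
})
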