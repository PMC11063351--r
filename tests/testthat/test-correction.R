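test_that("ratio screening uses inclusive bounds and flags undefined cells", {
  expect_false(screen(0.55))
  expect_true(screen(2.17))
  expect_true(screen(0.5))    # inclusive lower bound
  expect_true(screen(2))      # inclusive upper bound
  expect_false(screen(0.5000001))
  expect_true(screen(NA))
  expect_true(screen(0))
  # symmetric under ratio -> 1/ratio when low = 1/high
  for (r in c(0.1, 0.5, 0.7, 1, 1.9, 2, 5))
    expect_equal(screen(r), screen(1 / r))
})

test_that("ratio table computes, rounds and flags per the screening rule", {
  calc <- data.frame(dish_name = c("a", "b", "c"), category = "x",
                     method = "boiling",
                     fat = c(0.62, 0, 5), protein = c(3.41, 1, 1),
                     sodium = c(0.0005, 0.1, 0.1),
                     carbohydrate = c(37.47, 1, 1))
  det <- data.frame(dish_name = c("a", "b", "c"), category = "x",
                    method = "boiling",
                    fat = c(1.12, 2, 0), protein = c(3.16, 1, 1),
                    sodium = c(0.0014, 0.1, 0.1),
                    carbohydrate = c(59.73, 1, 1))
  rt <- ratio_table(paired_observations(calc, det))
  a <- rt[rt$dish_name == "a", ]
  expect_equal(a$value[a$nutrient == "fat"], 0.55)
  expect_false(a$flagged[a$nutrient == "fat"])
  expect_equal(a$value[a$nutrient == "protein"], 1.08)
  expect_equal(a$value[a$nutrient == "sodium"], 0.36)
  expect_true(a$flagged[a$nutrient == "sodium"])

  # calculated 0 -> ratio 0, flagged; detected 0 -> undefined, flagged
  b <- rt[rt$dish_name == "b" & rt$nutrient == "fat", ]
  expect_equal(b$ratio, 0)
  expect_true(b$flagged)
  expect_equal(b$display, "0.00*")
  c_ <- rt[rt$dish_name == "c" & rt$nutrient == "fat", ]
  expect_true(is.na(c_$ratio))
  expect_true(c_$flagged)
  expect_false(c_$defined)
  expect_equal(c_$display, "undef*")
})

test_that("flags come from unrounded ratios, not the printed rounding", {
  calc <- data.frame(dish_name = c("u", "v"), category = "x",
                     method = "boiling", fat = c(0.4967, 2.0024),
                     protein = 1, sodium = 0.1, carbohydrate = 1)
  det <- data.frame(dish_name = c("u", "v"), category = "x",
                    method = "boiling", fat = c(1, 1),
                    protein = 1, sodium = 0.1, carbohydrate = 1)
  rt <- ratio_table(paired_observations(calc, det))
  fat <- rt[rt$nutrient == "fat", ]
  expect_equal(fat$display, c("0.50*", "2.00*"))
})

test_that("pairing aligns by name or position and reports orphans", {
  calc <- data.frame(dish_name = c("a", "b"), category = "x",
                     method = "boiling", fat = 1, protein = 1, sodium = 1,
                     carbohydrate = 1)
  det <- calc; det$dish_name <- c("a", "z")
  expect_error(paired_observations(calc, det), "z",
               class = "alignment_error")
  expect_s3_class(paired_observations(calc, det, by = "position"),
                  "paired_observations")
  expect_error(paired_observations(calc, det[1, ], by = "position"),
               class = "alignment_error")
  det2 <- calc; det2$fat <- -1
  expect_error(paired_observations(calc, det2), class = "validation_error")
})

test_that("factor derivation activates only on flagged keys", {
  calc <- data.frame(dish_name = c("a", "b"), category = "x",
                     method = "boiling",
                     fat = c(10, 10), protein = c(10, 10),
                     sodium = c(1, 1), carbohydrate = c(10, 10))
  det <- data.frame(dish_name = c("a", "b"), category = "x",
                    method = "boiling",
                    fat = c(5, 5),          # ratio 2 -> flagged
                    protein = c(11.6, 11.6),  # ratio 0.86 -> unflagged
                    sodium = c(1, 1), carbohydrate = c(10, 10))
  m <- correction_model(paired_observations(calc, det))
  f <- m$factors
  fat <- f[f$nutrient == "fat", ]
  expect_true(fat$active)
  expect_equal(fat$factor, 0.5)        # detected / calculated
  expect_equal(fat$n_support, 2)
  prot <- f[f$nutrient == "protein", ]
  expect_false(prot$active)
  expect_equal(prot$factor, 1)

  # singleton-support active factor reproduces its detected value exactly
  p1 <- paired_observations(calc[1, ], det[1, ])
  m1 <- correction_model(p1)
  pred <- predict(m1, newdata = p1)
  flagged <- pred[pred$nutrient == "fat", ]
  expect_lt(abs(flagged$corrected - flagged$detected), 1e-9)
  expect_lt(max(abs(residuals(m1)[m1$ratio_table$flagged])), 1e-9)
})

test_that("keys with only degenerate cells warn and stay at factor 1", {
  calc <- data.frame(dish_name = "a", category = "x", method = "boiling",
                     fat = 0, protein = 1, sodium = 1, carbohydrate = 1)
  det <- calc; det$fat <- 2
  expect_warning(m <- correction_model(paired_observations(calc, det)),
                 "underivable")
  fat <- m$factors[m$factors$nutrient == "fat", ]
  expect_equal(fat$factor, 1)
  expect_false(fat$active)
})

test_that("a known multiplicative bias is recovered and correction helps", {
  pairs <- biased_pairs(n = 20, bias = 3, noise_sd = 0.05, seed = 11)
  m <- correction_model(pairs)
  f <- m$factors
  expect_true(all(f$active))
  # closed-form oracle: the mean of the generated detected/calculated cells
  for (nut in unique(f$nutrient)) {
    oracle <- mean(pairs[[paste0("det_", nut)]] /
                     pairs[[paste0("calc_", nut)]])
    expect_equal(f$factor[f$nutrient == nut], oracle)
    expect_lt(abs(f$factor[f$nutrient == nut] - 1 / 3), 0.05 / 3)
  }
  v <- validate_correction(pairs, m)
  overall <- v$table[v$table$nutrient == "overall", ]
  expect_lt(overall$mape_after, overall$mape_before)
  expect_false(any(v$table$error_increased))
})

test_that("identity factors leave the validation untouched", {
  pairs <- biased_pairs(n = 10, bias = 1, noise_sd = 0.3, seed = 12)
  m <- correction_model(pairs)   # ratios near 1 with wide noise: some flags
  identity <- m
  identity$factors$factor <- 1
  v <- validate_correction(pairs, identity)
  expect_equal(v$table$mae_before, v$table$mae_after)
  expect_equal(v$table$mape_before, v$table$mape_after)
})

test_that("correction model methods expose factors in standard ways", {
  pairs <- biased_pairs(n = 5, bias = 3, noise_sd = 0, seed = 13)
  m <- correction_model(pairs)
  cf <- coef(m)
  expect_true(all(abs(cf - 1 / 3) < 1e-9))
  expect_named(cf)
  expect_match(names(cf)[1], "synthetic:stir_frying:")
  s <- summary(m)
  expect_s3_class(s, "summary.correction_model")
  expect_equal(sum(s$per_nutrient$n_active), sum(m$factors$active))
  out <- capture.output(print(m))
  expect_true(any(grepl("active", out)))

  path <- tempfile(fileext = ".csv")
  write_correction_factors(m, path)
  back <- read_correction_factors(path)
  expect_equal(back$factor, m$factors$factor)
})

test_that("half-up rounding matches the print convention", {
  expect_equal(round_half_up(0.005, 2), 0.01)
  expect_equal(round_half_up(0.015, 2), 0.02)
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(-0.005, 2), -0.01)
  expect_equal(round_half_up(0.494999, 2), 0.49)
})
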