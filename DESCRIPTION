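Package: dishlabel
Title: Nutrition Calculation and Labeling for Cooked Catering Dishes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes per-100 g-cooked nutrient content and nutrition labels
    for catering dishes from raw-ingredient composition data, raw-to-cooked
    yield ratios, and added seasonings. Provides a food composition database
    with subclass representative values and fallback resolution for novel
    ingredient varieties, a raw-to-cooked ratio database keyed by food
    category and cooking method, a label engine with energy and nutrient
    reference value (NRV) percentages, and a correction-factor model that
    screens calculated-versus-detected nutrient ratios to derive and apply
    multiplicative cooking-method corrections. Includes packaged measurement
    tables, synthetic-data generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
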