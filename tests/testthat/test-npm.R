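th <- default_thresholds()

random_panels <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    product_id = paste0("r", seq_len(n)),
    energy_kcal = runif(n, 10, 900),
    total_fat_g = runif(n, 0, 40),
    saturated_fat_g = runif(n, 0, 20),
    trans_fat_g = runif(n, 0, 2),
    sodium_mg = runif(n, 0, 2000)
  )
}

test_that("all-zero critical nutrients produce no excess flags", {
  p <- product_record("z", "Cookies", energy_kcal = 100, total_sugars_g = 0)
  ex <- evaluate_excess(p, free_sugars_g = 0)
  expect_false(any(unlist(ex)))
})

test_that("a panel exactly at a threshold is in excess (documented >= convention)", {
  # 100 kcal; free sugar at exactly 10% of energy = 2.5 g
  p <- product_record("b", "Cookies", energy_kcal = 100)
  ex <- evaluate_excess(p, free_sugars_g = 2.5)
  expect_true(ex$excess_free_sugar)
  expect_false(ex$excess_total_fat)
  # sodium at exactly 1 mg/kcal
  p2 <- product_record("b2", "Cookies", energy_kcal = 100, sodium_mg = 100)
  ex2 <- evaluate_excess(p2, free_sugars_g = NA)
  expect_true(ex2$excess_sodium)
  expect_true(is.na(ex2$excess_free_sugar))
})

test_that("excess flags equal the independently coded ratio oracle on random panels", {
  panels <- random_panels(2000, 403)
  free <- ifelse(runif(2000) < 0.5, runif(2000, 0, 30), NA)
  got <- evaluate_excess(panels, free, th)
  want <- t(mapply(
    oracle_excess_row,
    panels$energy_kcal, free, panels$total_fat_g,
    panels$saturated_fat_g, panels$trans_fat_g, panels$sodium_mg,
    MoreArgs = list(th = th)
  ))
  expect_equal(unname(as.matrix(got)), unname(want))
})

test_that("flags are invariant to rescaling the declared basis", {
  panels <- random_panels(300, 404)
  free <- runif(300, 0, 20)
  base <- evaluate_excess(panels, free, th)
  for (c_scale in c(0.3, 2.5, 10)) {
    scaled <- panels
    for (cl in c("energy_kcal", "total_fat_g", "saturated_fat_g",
                 "trans_fat_g", "sodium_mg")) {
      scaled[[cl]] <- scaled[[cl]] * c_scale
    }
    expect_equal(evaluate_excess(scaled, free * c_scale, th), base)
  }
})

test_that("raising one nutrient at fixed energy never clears its excess flag", {
  panels <- random_panels(200, 405)
  free <- runif(200, 0, 20)
  base <- evaluate_excess(panels, free, th)
  bumped <- panels
  bumped$sodium_mg <- bumped$sodium_mg * 1.5
  after <- evaluate_excess(bumped, free, th)
  expect_true(all(after$excess_sodium >= base$excess_sodium))
  after2 <- evaluate_excess(panels, free * 2, th)
  expect_true(all(after2$excess_free_sugar >= base$excess_free_sugar))
})

test_that("missing or non-positive energy errors by default and is NA-flagged on request", {
  p <- product_record("e", "Soda", energy_kcal = 0)
  expect_error(evaluate_excess(p, 0), "not evaluable")
  ex <- evaluate_excess(p, 0, on_invalid_energy = "not_evaluable")
  expect_true(all(is.na(unlist(ex))))
})

test_that("eligibility and culinary filtering match an exhaustive truth-table oracle", {
  grid <- expand.grid(
    e1 = c(TRUE, FALSE, NA), e2 = c(TRUE, FALSE), e3 = c(TRUE, FALSE),
    e4 = c(TRUE, FALSE), e5 = c(TRUE, FALSE),
    a_sugar = c(TRUE, FALSE), a_salt = c(TRUE, FALSE), a_fat = c(TRUE, FALSE),
    culinary = c(TRUE, FALSE),
    category = c("Oils and Fats", "Sugar and Nonnutritive Sweeteners", "Cookies"),
    stringsAsFactors = FALSE
  )
  excess <- tibble::tibble(
    excess_free_sugar = grid$e1, excess_total_fat = grid$e2,
    excess_sat_fat = grid$e3, excess_trans_fat = grid$e4,
    excess_sodium = grid$e5
  )
  additions <- tibble::tibble(
    added_sugar = grid$a_sugar, added_salt = grid$a_salt,
    added_fat = grid$a_fat, nns = FALSE
  )
  prof <- apply_eligibility(excess, additions, grid$culinary, grid$category)
  for (i in seq_len(nrow(grid))) {
    want <- oracle_eligibility(
      unlist(excess[i, ]),
      c(grid$a_sugar[i], grid$a_salt[i], grid$a_fat[i]),
      grid$culinary[i],
      culinary_intrinsic_nutrients(grid$category[i])[[1]]
    )
    expect_equal(prof$eligible[i], want$eligible)
    expect_setequal(prof$warnings[[i]], want$warnings)
    expect_equal(prof$high_in_any[i], want$high_in_any)
  }
  # eligibility gate: no additions => no warnings, always
  none <- additions
  none$added_sugar <- none$added_salt <- none$added_fat <- FALSE
  prof0 <- apply_eligibility(excess, none, grid$culinary, grid$category)
  expect_true(all(lengths(prof0$warnings) == 0))
})

test_that("butter in excess for fats and sodium with added salt is warned for sodium only", {
  butter <- product_record("butter", "Oils and Fats",
    energy_kcal = 720, total_fat_g = 80, saturated_fat_g = 52,
    sodium_mg = 900,
    ingredients_text = "creme de leite, sal",
    is_culinary = TRUE
  )
  prof <- profile_products(butter)
  expect_true(prof$excess_total_fat)
  expect_true(prof$excess_sat_fat)
  expect_true(prof$excess_sodium)
  expect_true(prof$eligible)
  expect_identical(prof$warnings[[1]], "sodium")
  expect_true(prof$high_in_any)
})

test_that("the composed pipeline equals its stage-by-stage composition", {
  gen <- generate_products(generator_config(n = 1500, seed = 406))
  prods <- gen$products
  piped <- profile_products(prods)
  additions <- screen_ingredients(prods$ingredients_text, collect_matches = FALSE)
  free <- estimate_free_sugars(
    prods$total_sugars_g, prods$category, additions$added_sugar
  )
  excess <- evaluate_excess(prods, free, on_invalid_energy = "not_evaluable")
  manual <- apply_eligibility(excess, additions, prods$is_culinary, prods$category)
  expect_equal(piped$high_in_any, manual$high_in_any)
  expect_equal(piped$eligible, manual$eligible)
  expect_equal(piped$warnings, manual$warnings)
  expect_equal(piped$free_sugars_g, free)
  # empty input yields an empty profile table
  expect_equal(nrow(profile_products(prods[0, ])), 0)
})
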