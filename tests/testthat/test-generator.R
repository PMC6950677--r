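test_that("n = 0 yields empty outputs and a fixed seed reproduces identical output", {
  g0 <- generate_products(generator_config(n = 0, seed = 1))
  expect_equal(nrow(g0$products), 0)
  expect_equal(nrow(g0$truth), 0)
  g1 <- generate_products(generator_config(n = 300, seed = 5))
  g2 <- generate_products(generator_config(n = 300, seed = 5))
  expect_identical(g1, g2)
  g3 <- generate_products(generator_config(n = 300, seed = 6))
  expect_false(identical(g1$products$energy_kcal, g3$products$energy_kcal))
})

test_that("generated records satisfy every product invariant", {
  gen <- generate_products(generator_config(n = 2000, seed = 418))
  ok <- validate_products(gen$products, quiet = TRUE)
  expect_equal(nrow(ok), 2000)
  expect_equal(nrow(attr(ok, "rejected")), 0)
  p <- gen$products
  expect_true(all(p$energy_kcal > 0))
  expect_true(all(p$saturated_fat_g <= p$total_fat_g + 1e-12))
  expect_true(all(is.na(p$total_sugars_g) | p$total_sugars_g >= 0))
  expect_true(all(p$category %in% fop_categories()))
  expect_true(all(p$is_culinary == default_is_culinary(p$category)))
})

test_that("ground truth is emitted separately and the product table leaks none of it", {
  gen <- generate_products(generator_config(n = 50, seed = 419))
  truth_cols <- c(
    "added_sugar", "added_salt", "added_fat", "nns", "high_in_any",
    "claim_any", "claim_health", "claim_nutrition", "claim_environment"
  )
  expect_true(all(truth_cols %in% names(gen$truth)))
  expect_false(any(truth_cols %in% names(gen$products)))
})

test_that("invalid configurations are rejected up front", {
  expect_error(generator_config(n = 100), "seed is mandatory")
  expect_error(generator_config(n = 100, seed = 1, p_any_claim = 1.4), "\\[0, 1\\]")
  expect_error(
    generator_config(n = 100, seed = 1, category_weights = c(Soda = 1)),
    "25 categories"
  )
  expect_error(
    generator_config(
      n = 100, seed = 1,
      p_major = c(health = 0.1, nutrition = 0.15, environment = 0.05),
      p_any_claim = 0.4
    ),
    "sum"
  )
})

test_that("the conditional claim allocation solves the marginal equations", {
  p_any <- 0.412
  p_major <- c(health = 0.221, nutrition = 0.285, environment = 0.052)
  q <- solve_claim_allocation(p_any, p_major)
  # q_m / (1 - prod(1 - q)) must equal p_m / p_any
  c_star <- 1 - prod(1 - q)
  expect_equal(unname(q / c_star), unname(p_major / p_any), tolerance = 1e-8)
})

test_that("the calibration report's closed-form marginals match large-n simulation", {
  cfg <- generator_config(n = 30000, seed = 420)
  rep <- calibration_report(cfg)
  gen <- generate_products(cfg)
  t <- gen$truth
  observed <- c(
    claim_any = mean(t$claim_any),
    claim_health = mean(t$claim_health),
    claim_nutrition = mean(t$claim_nutrition),
    claim_environment = mean(t$claim_environment),
    sugar_declared = mean(t$sugars_declared),
    high_in_any = mean(t$high_in_any)
  )
  for (i in seq_len(nrow(rep))) {
    p <- rep$implied[i]
    se <- sqrt(p * (1 - p) / 30000)
    expect_lt(abs(observed[[rep$quantity[i]]] - p), 3 * se + 1e-9)
  }
  # a perturbed configuration still reports consistent implied marginals
  cfg2 <- generator_config(
    n = 30000, seed = 421, p_any_claim = 0.35,
    p_major = c(health = 0.25, nutrition = 0.2, environment = 0.08),
    p_sugar_declared = 0.2,
    p_high_given_nutrition = 0.7, p_high_given_no_nutrition = 0.4
  )
  rep2 <- calibration_report(cfg2)
  gen2 <- generate_products(cfg2)
  t2 <- gen2$truth
  obs2 <- c(
    claim_any = mean(t2$claim_any), claim_health = mean(t2$claim_health),
    claim_nutrition = mean(t2$claim_nutrition),
    claim_environment = mean(t2$claim_environment),
    sugar_declared = mean(t2$sugars_declared),
    high_in_any = mean(t2$high_in_any)
  )
  for (i in seq_len(nrow(rep2))) {
    p <- rep2$implied[i]
    se <- sqrt(p * (1 - p) / 30000)
    expect_lt(abs(obs2[[rep2$quantity[i]]] - p), 3.5 * se + 1e-9)
  }
})

test_that("a degenerate one-category configuration has that category's implied marginal", {
  w <- setNames(rep(0, 25), fop_categories())
  w["Cookies"] <- 1
  cfg <- generator_config(n = 10, seed = 2, category_weights = w)
  rep <- calibration_report(cfg)
  expect_equal(
    rep$implied[rep$quantity == "claim_any"],
    unname(cfg$p_any_cat[fop_categories() == "Cookies"])
  )
  gen <- generate_products(cfg)
  expect_true(all(gen$products$category == "Cookies"))
})

test_that("the full pipeline recovers planted flags and status exactly (end-to-end identifiability)", {
  gen <- generate_products(generator_config(n = 2500, seed = 422))
  prof <- profile_products(gen$products)
  ann <- annotate_product_claims(gen$products)
  expect_equal(prof$added_sugar, gen$truth$added_sugar)
  expect_equal(prof$added_salt, gen$truth$added_salt)
  expect_equal(prof$added_fat, gen$truth$added_fat)
  expect_equal(prof$nns, gen$truth$nns)
  expect_equal(prof$high_in_any, gen$truth$high_in_any)
  expect_equal(prof$excess_sodium, gen$truth$excess_sodium)
  expect_equal(prof$excess_free_sugar, gen$truth$excess_free_sugar)
  expect_equal(ann$claim_any, gen$truth$claim_any)
  expect_equal(ann$claim_nutrition, gen$truth$claim_nutrition)
})

test_that("noisy-text mode degrades claim recovery without touching ground truth", {
  cfg <- generator_config(n = 1500, seed = 423, noisy_text_rate = 0.5)
  gen <- generate_products(cfg)
  ann <- annotate_product_claims(gen$products)
  hits <- mean(ann$claim_any == gen$truth$claim_any)
  expect_lt(hits, 1)
  expect_gt(hits, 0.5)
  expect_equal(mean(gen$truth$claim_any) > 0.3, TRUE)
})
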