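test_that("Wilson interval behaves correctly at the boundaries", {
  at0 <- prevalence_ci(0, 10)
  expect_equal(at0$p, 0)
  expect_equal(at0$lo, 0)
  expect_gt(at0$hi, 0)
  at1 <- prevalence_ci(10, 10)
  expect_equal(at1$p, 1)
  expect_equal(at1$hi, 1)
  expect_lt(at1$lo, 1)
  expect_error(prevalence_ci(1, 0), "denominator")
  expect_error(prevalence_ci(5, 3), "k <= n")
})

test_that("Wilson limits equal the prop.test score interval over a (k, n) grid", {
  for (n in c(5, 20, 100, 1000)) {
    for (k in unique(round(c(0, 1, n / 4, n / 2, n - 1, n)))) {
      got <- prevalence_ci(k, n)
      want <- oracle_wilson(k, n)
      expect_equal(c(got$lo, got$hi), want, tolerance = 1e-10)
    }
  }
})

test_that("the exact (Clopper-Pearson) method is available and recorded", {
  got <- prevalence_ci(3, 10, method = "exact")
  bt <- stats::binom.test(3, 10)$conf.int
  expect_equal(c(got$lo, got$hi), as.numeric(bt), tolerance = 1e-10)
  expect_equal(got$method, "exact")
  expect_equal(prevalence_ci(3, 10)$method, "wilson")
})

test_that("the claim prevalence table has exact counts on an enumerable fixture", {
  prods <- fixture_products()
  ann <- annotate_product_claims(prods)
  tab <- claim_prevalence_table(prods, ann)
  overall <- tab[tab$category == "Overall", ]
  # f1: nutrition; f2: nutrition+environment; f5: health; f6: nutrition
  expect_equal(overall$k[overall$claim_type == "claim_any"], 4)
  expect_equal(overall$k[overall$claim_type == "claim_nutrition"], 3)
  expect_equal(overall$k[overall$claim_type == "claim_health"], 1)
  expect_equal(overall$k[overall$claim_type == "claim_environment"], 1)
  expect_true(all(overall$n == 6))
  # per-category rows sum to the overall numerator
  by_cat <- tab[tab$category != "Overall" & tab$claim_type == "claim_any", ]
  expect_equal(sum(by_cat$k), 4)
  expect_equal(sum(by_cat$n), 6)
  # empty categories are emitted with n = 0, not dropped
  expect_true(all(fop_categories() %in% by_cat$category))
  expect_true(any(by_cat$n == 0 & is.na(by_cat$p)))
  # claim types are not mutually exclusive: per-type sum exceeds any-claim
  k_types <- overall$k[overall$claim_type != "claim_any"]
  expect_gte(sum(k_types), overall$k[overall$claim_type == "claim_any"])
})

test_that("the with/without-claim comparison detects symmetry and independence", {
  # all products high: both arms at p = 1, intervals overlap
  ann <- tibble::tibble(
    product_id = paste0("p", 1:8),
    claim_any = rep(c(TRUE, FALSE), 4),
    claim_health = rep(c(TRUE, FALSE), 4),
    claim_nutrition = FALSE, claim_environment = FALSE,
    health_general = FALSE, health_special_diets = FALSE,
    health_natural = FALSE, health_others = FALSE,
    nutrition_of_concern = FALSE, nutrition_not_of_concern = FALSE,
    nutrition_others = FALSE, environment_environment = FALSE
  )
  prof <- tibble::tibble(
    product_id = paste0("p", 1:8), category = "Cookies",
    high_in_any = TRUE
  )
  tab <- warning_by_claim_table(ann, prof, claim_cols = "claim_health")
  expect_equal(c(tab$p_yes, tab$p_no), c(1, 1))
  expect_false(tab$ci_nonoverlap)
  # claim independent of warning with equal cells: equal proportions
  prof2 <- prof
  prof2$high_in_any <- rep(c(TRUE, TRUE, FALSE, FALSE), 2)
  tab2 <- warning_by_claim_table(ann, prof2, claim_cols = "claim_health")
  expect_equal(tab2$p_yes, tab2$p_no)
  # join failure is reported with the offending id
  expect_error(
    warning_by_claim_table(ann, prof[-1, ], claim_cols = "claim_health"),
    "p1"
  )
})

test_that("wilson coverage over a probability grid is near nominal", {
  set.seed(416)
  for (p in c(0.05, 0.3, 0.5, 0.9)) {
    n <- 80
    k <- rbinom(4000, n, p)
    ci <- prevalence_ci(k, n)
    cover <- mean(ci$lo <= p & p <= ci$hi)
    expect_gte(cover, 0.93)
    expect_lte(cover, 0.97)
  }
})

test_that("the per-category stratified sampler draws the requested fraction with a seed", {
  gen <- generate_products(generator_config(n = 1200, seed = 417))
  set.seed(1)
  s1 <- sample_by_category(gen$products, 0.3)
  set.seed(1)
  s2 <- sample_by_category(gen$products, 0.3)
  expect_identical(s1, s2)
  by_cat <- table(gen$products$category)
  got <- table(factor(s1$category, levels = names(by_cat)))
  expect_true(all(abs(as.numeric(got) - pmax(1, round(0.3 * as.numeric(by_cat)))) == 0))
})

test_that("run_full_analysis is byte-identical across runs at a fixed seed", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- list(seed = 99, generator = list(n = 400, seed = 99), out_dir = dir1)
  run_full_analysis(cfg)
  run_full_analysis(utils::modifyList(cfg, list(out_dir = dir2)))
  files <- list.files(dir1)
  expect_true(length(files) >= 5)
  for (f in files) {
    b1 <- readBin(file.path(dir1, f), "raw", file.size(file.path(dir1, f)))
    b2 <- readBin(file.path(dir2, f), "raw", file.size(file.path(dir2, f)))
    expect_identical(b1, b2)
  }
  expect_error(
    run_full_analysis(list(seed = 1, generator = list(n = 0, seed = 1))),
    "positive"
  )
})

test_that("report totals equal stage-level recomputation on the same records", {
  res <- run_full_analysis(list(seed = 55, generator = list(n = 600, seed = 55)))
  ann <- annotate_product_claims(res$products)
  prof <- profile_products(res$products)
  overall_any <- res$claim_prevalence[
    res$claim_prevalence$category == "Overall" &
      res$claim_prevalence$claim_type == "claim_any",
  ]
  expect_equal(overall_any$k, sum(ann$claim_any))
  fig2_nut <- res$warning_by_claim[
    res$warning_by_claim$claim_type == "claim_nutrition",
  ]
  expect_equal(fig2_nut$k_yes, sum(prof$high_in_any & ann$claim_nutrition))
  expect_equal(fig2_nut$n_yes, sum(ann$claim_nutrition))
  # every cell's numerator bounded by its stratum denominator
  expect_true(all(res$warning_by_claim_category$k_yes <=
    res$warning_by_claim_category$n_yes))
  strat <- res$claims_by_excess
  expect_true(all(strat$k <= strat$n))
  high_sodium <- prof$product_id[!is.na(prof$excess_sodium) & prof$excess_sodium]
  row <- strat[strat$excess_nutrient == "sodium" & strat$claim_type == "claim_health", ]
  expect_equal(row$n, length(high_sodium))
  expect_equal(row$k, sum(ann$claim_health[ann$product_id %in% high_sodium]))
})
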