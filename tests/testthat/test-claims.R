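clex <- default_claim_lexicon()

test_that("segments resolve through the hierarchy: health over nutrition over environment", {
  both <- classify_claim("produto saudável com zero açúcar", clex)
  expect_equal(both$major, "health")
  nut_env <- classify_claim("zero açúcar e orgânico", clex)
  expect_equal(nut_env$major, "nutrition")
  all3 <- classify_claim("saudável, zero açúcar, orgânico", clex)
  expect_equal(all3$major, "health")
})

test_that("single-cell patterns classify to their published taxonomy cell", {
  expect_equal(
    classify_claim("orgânico", clex)[, c("major", "sub")],
    tibble::tibble(major = "environment", sub = "environment")
  )
  expect_equal(classify_claim("fonte de fibras", clex)$sub, "not_of_concern")
  expect_equal(classify_claim("sem gordura trans", clex)$sub, "of_concern")
  expect_equal(classify_claim("sem glúten", clex)$sub, "special_diets")
  expect_equal(classify_claim("qualidade garantida desde 1950", clex)$major, "none")
})

test_that("every lexicon pattern classifies back to exactly its own cell", {
  ann <- classify_claim(clex$pattern, clex)
  expect_equal(ann$major, clex$major)
  expect_equal(ann$sub, clex$sub)
})

test_that("classification is idempotent and deterministic", {
  texts <- c(clex$pattern[seq(1, nrow(clex), 3)], "texto neutro")
  a1 <- classify_claim(texts, clex)
  a2 <- classify_claim(a1$text, clex)
  expect_identical(a1, a2)
})

test_that("nutrients of concern are exactly saturated fat, trans fat, sugar, sodium", {
  of_concern <- c("saturated_fat", "trans_fat", "sugar", "sodium")
  not_of_concern <- c("fiber", "vitamins", "minerals", "unsaturated_fat", "protein")
  expect_true(all(is_nutrient_of_concern(of_concern)))
  expect_false(any(is_nutrient_of_concern(not_of_concern)))
  expect_error(is_nutrient_of_concern("caffeine"), "unknown nutrient")
})

test_that("per-product indicators OR over segments and ignore ingredient text", {
  p <- dplyr::bind_rows(
    product_record("m1", "Cookies", 460,
      ingredients_text = "açúcar, óleo vegetal",  # would be claims if scanned
      fop_texts = c("saudável", "orgânico")
    ),
    product_record("m2", "Cookies", 460, fop_texts = character(0)),
    product_record("m3", "Soda", 40, fop_texts = c("zero açúcar", "rico em vitaminas"))
  )
  ann <- annotate_product_claims(p)
  expect_true(ann$claim_health[1] && ann$claim_environment[1])
  expect_false(ann$claim_nutrition[1])
  expect_false(ann$claim_any[2])
  expect_true(ann$nutrition_of_concern[3] && ann$nutrition_not_of_concern[3])
  # monotone in fop_texts: adding a segment never clears an indicator
  p_more <- p
  p_more$fop_texts[[2]] <- "vegano"
  ann_more <- annotate_product_claims(p_more)
  ind <- setdiff(names(ann), "product_id")
  expect_true(all(as.matrix(ann_more[, ind]) >= as.matrix(ann[, ind])))
})

test_that("coded-input mode reproduces lexicon-mode indicators", {
  gen <- generate_products(generator_config(n = 400, seed = 408))
  ann <- annotate_product_claims(gen$products)
  segs <- classify_claim(unlist(gen$products$fop_texts), clex)
  owner <- rep(gen$products$product_id, lengths(gen$products$fop_texts))
  coded <- tibble::tibble(product_id = owner, major = segs$major, sub = segs$sub)
  ann2 <- annotate_coded_claims(coded, product_ids = gen$products$product_id)
  expect_equal(ann, ann2)
})

test_that("planted claim labels are recovered exactly on generator output", {
  gen <- generate_products(generator_config(n = 1000, seed = 409))
  ann <- annotate_product_claims(gen$products)
  expect_equal(ann$claim_any, gen$truth$claim_any)
  expect_equal(ann$claim_health, gen$truth$claim_health)
  expect_equal(ann$claim_nutrition, gen$truth$claim_nutrition)
  expect_equal(ann$claim_environment, gen$truth$claim_environment)
  # subcategory-level recovery
  planted <- gen$truth$health_sub
  has <- !is.na(planted)
  for (sb in unique(planted[has])) {
    expect_equal(
      ann[[paste0("health_", sb)]][has & planted == sb],
      rep(TRUE, sum(has & planted == sb))
    )
  }
})
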