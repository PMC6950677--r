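#' Excess thresholds for the nutrient profile model
#'
#' The profile model flags a product as containing an excessive amount of a
#' critical nutrient when the nutrient's share of energy (or, for sodium,
#' the sodium-to-energy density) reaches a threshold. Because the rules are
#' ratios to energy, they are invariant to the declared basis (per 100 g or
#' per portion). Thresholds ship as configuration with a provenance note,
#' never as hard-coded constants; the default file carries the cited
#' model's recommendations: free sugars ≥ 10% of energy, total fat ≥ 30%,
#' saturated fat ≥ 10%, trans fat ≥ 1%, sodium ≥ 1 mg/kcal, with energy
#' conversion factors 4 kcal/g (sugars) and 9 kcal/g (fats). The boundary
#' uses ≥ (a panel exactly at a threshold is in excess).
#'
#' @param path Path to a thresholds YAML file.
#' @return Threshold configuration: list with `provenance`, `energy_share`
#'   (named: free_sugar, total_fat, sat_fat, trans_fat), `sodium_mg_per_kcal`,
#'   `kcal_per_g` (sugar, fat), `track_nns`, `nns_in_high_in_any`.
#' @export
read_thresholds <- function(path) {
  th <- yaml::read_yaml(path)
  needed <- c("energy_share", "sodium_mg_per_kcal", "kcal_per_g")
  missing <- needed[!needed %in% names(th)]
  if (length(missing) > 0) {
    stop("threshold file lacks keys: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  stopifnot(
    all(unlist(th$energy_share) > 0), th$sodium_mg_per_kcal > 0,
    all(unlist(th$kcal_per_g) > 0)
  )
  if (is.null(th$nns_in_high_in_any)) th$nns_in_high_in_any <- FALSE
  th
}

#' @rdname read_thresholds
#' @export
default_thresholds <- function() {
  read_thresholds(
    system.file("extdata", "npm_thresholds.yml",
      package = "foplabel", mustWork = TRUE
    )
  )
}

#' Evaluate per-nutrient excess flags
#'
#' Computes the five tri-state excess flags (TRUE / FALSE / NA =
#' not-evaluable) from a nutrition panel and an estimated free-sugar
#' amount. The free-sugar flag is `NA` when free sugars could not be
#' estimated (sugars not declared); a not-evaluable flag never counts as
#' excess. All comparisons are on nutrient-to-energy ratios, so the flags
#' do not depend on the declared basis.
#'
#' @param products Product table (only the panel columns are used).
#' @param free_sugars_g Estimated free sugars per basis, g (`NA` allowed).
#' @param thresholds Threshold configuration ([default_thresholds()]).
#' @param on_invalid_energy `"error"` (default) to reject panels with
#'   missing or non-positive energy; `"not_evaluable"` to return all-`NA`
#'   flags for such rows and keep going (used by [profile_products()]).
#' @return Tibble of logicals `excess_free_sugar`, `excess_total_fat`,
#'   `excess_sat_fat`, `excess_trans_fat`, `excess_sodium`.
#' @export
evaluate_excess <- function(products, free_sugars_g,
                            thresholds = default_thresholds(),
                            on_invalid_energy = c("error", "not_evaluable")) {
  on_invalid_energy <- match.arg(on_invalid_energy)
  energy <- products$energy_kcal
  bad <- is.na(energy) | energy <= 0
  if (any(bad) && on_invalid_energy == "error") {
    stop(
      "evaluate_excess: missing or non-positive energy for ",
      sum(bad), " product(s); such panels are not evaluable",
      call. = FALSE
    )
  }
  kc <- thresholds$kcal_per_g
  sh <- thresholds$energy_share
  energy_safe <- ifelse(bad, NA_real_, energy)
  out <- tibble::tibble(
    excess_free_sugar = kc$sugar * free_sugars_g / energy_safe >= sh$free_sugar,
    excess_total_fat = kc$fat * products$total_fat_g / energy_safe >= sh$total_fat,
    excess_sat_fat = kc$fat * products$saturated_fat_g / energy_safe >= sh$sat_fat,
    excess_trans_fat = kc$fat * products$trans_fat_g / energy_safe >= sh$trans_fat,
    excess_sodium = products$sodium_mg / energy_safe >= thresholds$sodium_mg_per_kcal
  )
  out
}

#' Apply the eligibility and culinary rules to excess flags
#'
#' Implements the modified profiling rule: a product is eligible to receive
#' "high in" warning signs only if its ingredient list shows added sugar,
#' added salt, or added fat (the Chilean-law criterion, operationalized via
#' the keyword screen). Culinary ingredients (sugar, salt, oils, butter,
#' milk creams) are never warned for the critical nutrients intrinsic to
#' their own identity: butter, in excess for both fats and sodium and with
#' added salt, receives the sodium warning only.
#'
#' `high_in_any` records whether any of the five excess flags is TRUE —
#' the product's nutritional profile — independent of eligibility;
#' `warnings` is the set of warning signs the product would actually
#' receive under the modified rule. Nonnutritive-sweetener presence is
#' tracked (`contains_nns`) but by default does not enter `high_in_any`
#' (configurable via the threshold file's `nns_in_high_in_any`).
#'
#' @param excess Tibble of excess flags from [evaluate_excess()].
#' @param additions Tibble of addition flags from [screen_ingredients()]
#'   (columns `added_sugar`, `added_salt`, `added_fat`, `nns`).
#' @param is_culinary Logical vector.
#' @param category Character vector of categories (used to resolve the
#'   culinary identity nutrients); `NULL` treats culinary products as
#'   having no identity nutrients.
#' @param thresholds Threshold configuration (for the NNS accounting flag).
#' @return Tibble: the excess flags, `contains_nns`, `eligible`,
#'   `high_in_any`, and `warnings` (list-column of nutrient tags).
#' @export
apply_eligibility <- function(excess, additions, is_culinary,
                              category = NULL,
                              thresholds = default_thresholds()) {
  n <- nrow(excess)
  eligible <- additions$added_sugar | additions$added_salt | additions$added_fat
  tags <- critical_nutrients()
  excess_mat <- as.matrix(excess[, paste0("excess_", c(
    "free_sugar", "total_fat", "sat_fat", "trans_fat", "sodium"
  ))])
  colnames(excess_mat) <- tags
  excess_true <- !is.na(excess_mat) & excess_mat
  high_in_any <- rowSums(excess_true) > 0
  if (isTRUE(thresholds$nns_in_high_in_any)) {
    high_in_any <- high_in_any | additions$nns
  }
  intrinsic <- if (is.null(category)) {
    rep(list(character(0)), n)
  } else {
    culinary_intrinsic_nutrients(category)
  }
  warnings <- lapply(seq_len(n), function(i) {
    if (!eligible[i]) {
      return(character(0))
    }
    w <- tags[excess_true[i, ]]
    if (isTRUE(is_culinary[i])) w <- setdiff(w, intrinsic[[i]])
    w
  })
  out <- tibble::as_tibble(excess)
  out$contains_nns <- additions$nns
  out$eligible <- eligible
  out$high_in_any <- high_in_any
  out$warnings <- warnings
  out
}

#' Profile a product table end to end
#'
#' Composes the three stages — ingredient keyword screen, free-sugar
#' estimation, excess evaluation plus eligibility/culinary rules — into one
#' warning profile per product. Stage outputs (addition flags, estimated
#' free sugars, excess flags) are all retained in the result for audit.
#' Products whose panel is not evaluable (missing/zero energy) come out
#' with all-`NA` excess flags and `high_in_any = FALSE` rather than
#' aborting the run.
#'
#' @param products A validated product table.
#' @param lexicon Ingredient keyword lexicon.
#' @param fraction_map Free-sugar fraction map.
#' @param thresholds Threshold configuration.
#' @param collect_matches Keep per-keyword match detail (slower).
#' @return Tibble with one row per product: `product_id`, `category`,
#'   addition flags, `free_sugars_g`, excess flags, `contains_nns`,
#'   `eligible`, `high_in_any`, `warnings` (list-column), `evaluable`.
#' @export
profile_products <- function(products,
                             lexicon = default_ingredient_lexicon(),
                             fraction_map = default_fraction_map(),
                             thresholds = default_thresholds(),
                             collect_matches = FALSE) {
  products <- as_product_table(products)
  additions <- screen_ingredients(products$ingredients_text, lexicon,
    collect_matches = collect_matches
  )
  free_sugars <- estimate_free_sugars(
    products$total_sugars_g, products$category, additions$added_sugar,
    fraction_map
  )
  excess <- evaluate_excess(products, free_sugars, thresholds,
    on_invalid_energy = "not_evaluable"
  )
  prof <- apply_eligibility(
    excess, additions, products$is_culinary, products$category, thresholds
  )
  out <- dplyr::bind_cols(
    tibble::tibble(
      product_id = products$product_id, category = products$category
    ),
    additions[, c("added_sugar", "added_salt", "added_fat", "nns")],
    tibble::tibble(free_sugars_g = free_sugars),
    prof
  )
  out$evaluable <- !is.na(products$energy_kcal) & products$energy_kcal > 0
  out
}
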