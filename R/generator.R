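#' Solve the conditional claim-type allocation
#'
#' The generator draws an any-claim indicator first, then assigns majors to
#' claim-carrying products. With target marginals for "any claim" and for
#' each major, the per-major assignment probabilities `q` (independent
#' Bernoulli conditioned on at least one major) must satisfy
#' `q_m / (1 - prod(1 - q)) = p_m / p_any`. That reduces to a scalar fixed
#' point `c = 1 - prod(1 - c * r_m)` with `r_m = p_m / p_any`, solved here
#' by root finding. Independent unconditional majors cannot reproduce the
#' observed marginals (41.2% any vs 28.5/22.1/5.2 per type implies positive
#' co-occurrence of claim types), hence this construction.
#'
#' @param p_any Target any-claim marginal.
#' @param p_major Named numeric: target marginals for `health`,
#'   `nutrition`, `environment`. Must each be < `p_any` and sum to more
#'   than `p_any`.
#' @return Named vector `q` of conditional assignment probabilities.
#' @export
solve_claim_allocation <- function(p_any, p_major) {
  stopifnot(p_any > 0, p_any < 1, all(p_major > 0), all(p_major <= p_any))
  r <- p_major / p_any
  if (sum(r) <= 1) {
    stop(
      "claim-type marginals sum to no more than the any-claim marginal; ",
      "the conditional allocation needs sum(p_major) > p_any",
      call. = FALSE
    )
  }
  f <- function(c) 1 - prod(1 - c * r) - c
  upper <- min(1, 1 / max(r)) - 1e-9
  c_star <- stats::uniroot(f, c(1e-9, upper), tol = 1e-12)$root
  q <- c_star * r
  names(q) <- names(p_major)
  q
}

#' @keywords internal
#' Per-category panel and addition parameters of the default generator.
#' Shares are nutrient-to-energy ratios (lognormal meanlog/sdlog); sodium
#' is mg/kcal. Presets are illustrative and qualitatively ordered (cookies
#' and processed meats usually in excess, packaged produce essentially
#' never), not fitted to any dataset.
generator_category_params <- function() {
  p <- function(category, e_ml, e_sl, su_ml, su_sl, fa_ml, fa_sl,
                sa_ml, sa_sl, tr_ml, tr_sl, so_ml, so_sl,
                p_sugar, p_salt, p_fat, p_nns, rel_claim) {
    tibble::tibble(
      category = category,
      energy_meanlog = log(e_ml), energy_sdlog = e_sl,
      sugar_meanlog = log(su_ml), sugar_sdlog = su_sl,
      fat_meanlog = log(fa_ml), fat_sdlog = fa_sl,
      sat_meanlog = log(sa_ml), sat_sdlog = sa_sl,
      trans_meanlog = log(tr_ml), trans_sdlog = tr_sl,
      sodium_meanlog = log(so_ml), sodium_sdlog = so_sl,
      p_add_sugar = p_sugar, p_add_salt = p_salt, p_add_fat = p_fat,
      p_nns = p_nns, rel_claim = rel_claim
    )
  }
  dplyr::bind_rows(
    p("Breakfast Cereals and Granola Bars", 380, .2, .30, .5, .12, .7, .05, .8, .001, 1, .9, .6, .90, .60, .40, .05, 2.2),
    p("Bakery Products", 300, .3, .15, .7, .25, .6, .10, .7, .004, 1.2, 1.3, .4, .80, .90, .80, .01, 1.0),
    p("Convenience Foods", 150, .5, .05, .8, .30, .5, .10, .6, .004, 1.2, 1.8, .5, .30, .95, .80, .00, 0.8),
    p("Unsweetened Dairy Products", 60, .4, .30, .4, .30, .6, .18, .6, .002, 1, .7, .5, .05, .20, .30, .02, 0.9),
    p("Sweetened Dairy Products", 90, .3, .50, .4, .25, .5, .15, .5, .002, 1, .6, .5, .90, .30, .50, .08, 1.25),
    p("Salty Snacks", 480, .2, .05, .8, .45, .4, .15, .5, .006, 1.2, 1.6, .5, .30, .95, .90, .00, 0.9),
    p("Cookies", 460, .15, .30, .4, .35, .4, .16, .5, .008, 1.2, .8, .5, .97, .80, .95, .02, 1.1),
    p("Canned Vegetables", 60, .5, .15, .8, .05, 1, .02, 1, .0002, 1, 1.5, .6, .20, .90, .30, .00, 0.7),
    p("Oils and Fats", 820, .15, .002, 1, .98, .05, .25, .5, .004, 1, .05, 1.5, .02, .30, .98, .00, 0.6),
    p("Sauces and Dressings", 120, .6, .20, .8, .30, .8, .06, .8, .0005, 1, 2.5, .5, .70, .97, .70, .02, 0.8),
    p("Coffee and Tea", 20, 1.0, .30, 1, .02, 1, .01, 1, .0002, 1, .2, 1, .20, .05, .05, .05, 0.5),
    p("Candies and Desserts", 380, .3, .60, .3, .20, .7, .12, .7, .003, 1.2, .3, .8, .98, .40, .70, .05, 0.6),
    p("Cereals, Beans, Other Grain Products", 350, .2, .02, 1, .03, 1, .01, 1, .0002, 1, .05, 1.5, .10, .20, .10, .00, 0.7),
    p("Packaged Fruits and Vegetables", 50, .5, .40, .5, .01, 1, .005, 1, .0002, 1, .1, 1, .02, .10, .05, .00, 0.8),
    p("Meat, Poultry, Seafood, and Egg", 150, .3, .01, 1, .30, .6, .10, .6, .001, 1, .6, .5, .02, .15, .10, .00, 0.4),
    p("Sugar and Nonnutritive Sweeteners", 390, .1, 1.00, .05, .002, 1, .001, 1, .0002, 1, .01, 2, .90, .05, .02, .30, 0.6),
    p("Processed Meats", 220, .3, .01, 1, .50, .4, .18, .5, .002, 1, 3.0, .4, .30, .98, .60, .00, 0.5),
    p("Juices", 45, .3, .95, .25, .01, .8, .005, .8, .0002, 1, .3, .7, .30, .05, .02, .05, 2.2),
    p("Nectars", 45, .3, .95, .25, .01, .8, .005, .8, .0002, 1, .3, .7, .85, .05, .02, .05, 2.1),
    p("Fruit-Flavored Drinks", 40, .3, 1.00, .25, .01, .8, .005, .8, .0002, 1, .5, .6, .95, .20, .05, .15, 2.0),
    p("Soda", 40, .3, 1.00, .25, .01, .8, .005, .8, .0002, 1, .5, .6, .95, .20, .05, .15, 1.0),
    p("Other Beverages", 50, .4, .70, .5, .05, .8, .02, .8, .0002, 1, .5, .6, .60, .20, .20, .10, 1.4),
    p("Nuts and Seeds", 560, .15, .04, 1, .65, .2, .12, .4, .0002, 1, .4, .9, .30, .50, .30, .00, 1.1),
    p("Cheese", 300, .3, .02, .8, .65, .3, .40, .3, .003, 1, 2.0, .4, .05, .95, .40, .00, 0.7),
    p("Fruit Preserve", 250, .3, .85, .2, .005, 1, .002, 1, .0002, 1, .05, 1.5, .90, .10, .05, .05, 0.9)
  )
}

#' @keywords internal
default_category_weights <- function() {
  w <- c(
    .03, .06, .08, .02, .06, .04, .06, .03, .03, .06, .03, .09, .06,
    .03, .03, .02, .05, .02, .02, .02, .02, .03, .02, .05, .04
  )
  setNames(w, fop_categories())
}

#' @keywords internal
#' Distractor ingredient tokens guaranteed not to match the default
#' keyword lexicon; includes false-positive traps (salsa vs sal, melão vs
#' mel) deliberately.
generator_distractors <- function() {
  c(
    "água", "farinha de trigo", "fermento químico", "salsa", "salsão",
    "melão", "melancia", "aveia integral", "arroz", "milho", "cacau em pó",
    "aroma artificial", "corante caramelo", "conservante", "espessante",
    "ácido cítrico", "tomate", "cebola", "alho", "pimenta do reino"
  )
}

#' Configuration for the synthetic label generator
#'
#' Builds and validates a generator configuration. Defaults reproduce the
#' study conditions the analysis assumes: 25 reporting categories, a 10%
#' total-sugar declaration rate, claim marginals of 41.2% (any), 28.5%
#' (nutrition), 22.1% (health) and 5.2% (environment), and a planted
#' association between nutrition claims and the high-in-any-critical-
#' nutrient status (65.3% among nutrition-claim products vs 54.1% among the
#' rest). Per-category claim prevalence varies around the overall marginal
#' by the relative pattern in the category parameter table, normalized so
#' the mixture equals `p_any_claim` exactly.
#'
#' @param n Number of products.
#' @param seed Integer seed; mandatory for reproducible generation.
#' @param category_weights Named numeric over [fop_categories()]
#'   (normalized internally).
#' @param p_any_claim Target any-claim marginal.
#' @param p_major Named targets for `health`, `nutrition`, `environment`.
#' @param p_sugar_declared Probability total sugars are declared.
#' @param p_high_given_nutrition,p_high_given_no_nutrition Planted
#'   conditional probabilities of being high in any critical nutrient.
#' @param sub_dist Per-major subcategory sampling distributions.
#' @param noisy_text_rate Fraction of claim segments replaced by
#'   paraphrases absent from the pattern lexicon (0 by default: classifier
#'   recovery is then exact by construction).
#' @param max_redraws Panel redraw rounds before deterministic forcing of
#'   the target high-in status.
#' @return A validated config list (class `fop_generator_config`).
#' @export
generator_config <- function(n = 3491, seed = NULL,
                             category_weights = default_category_weights(),
                             p_any_claim = 0.412,
                             p_major = c(
                               health = 0.221, nutrition = 0.285,
                               environment = 0.052
                             ),
                             p_sugar_declared = 0.10,
                             p_high_given_nutrition = 0.653,
                             p_high_given_no_nutrition = 0.541,
                             sub_dist = list(
                               health = c(
                                 general = .30, special_diets = .28,
                                 natural = .36, others = .06
                               ),
                               nutrition = c(
                                 of_concern = .446, not_of_concern = .460,
                                 others = .094
                               ),
                               environment = c(environment = 1)
                             ),
                             noisy_text_rate = 0,
                             max_redraws = 20) {
  stopifnot(n >= 0, n == round(n))
  if (is.null(seed)) stop("generator_config: seed is mandatory", call. = FALSE)
  cats <- fop_categories()
  if (!all(cats %in% names(category_weights))) {
    stop("category_weights must cover all 25 categories", call. = FALSE)
  }
  w <- category_weights[cats]
  if (any(w < 0) || sum(w) <= 0) {
    stop("category_weights must be non-negative with positive sum",
      call. = FALSE
    )
  }
  w <- w / sum(w)
  probs <- c(
    p_any_claim, p_major, p_sugar_declared,
    p_high_given_nutrition, p_high_given_no_nutrition, noisy_text_rate
  )
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  params <- generator_category_params()
  params <- params[match(cats, params$category), ]
  rel <- params$rel_claim
  p_any_cat <- p_any_claim * rel / sum(w * rel)
  if (any(p_any_cat > 1)) {
    stop(
      "infeasible config: per-category any-claim probability exceeds 1 for ",
      paste(cats[p_any_cat > 1], collapse = ", "),
      call. = FALSE
    )
  }
  q_major <- solve_claim_allocation(p_any_claim, p_major[c(
    "health", "nutrition", "environment"
  )])
  structure(
    list(
      n = as.integer(n), seed = as.integer(seed),
      category_weights = w, p_any_claim = p_any_claim,
      p_major = p_major, q_major = q_major, p_any_cat = p_any_cat,
      p_sugar_declared = p_sugar_declared,
      p_high_given_nutrition = p_high_given_nutrition,
      p_high_given_no_nutrition = p_high_given_no_nutrition,
      sub_dist = sub_dist, noisy_text_rate = noisy_text_rate,
      max_redraws = as.integer(max_redraws), params = params
    ),
    class = "fop_generator_config"
  )
}

#' @keywords internal
#' Direct excess computation on latent shares; mirrors the engine's
#' ratio comparisons (shares are already nutrient-to-energy ratios).
shares_excess <- function(sh, free_fraction, declared, thresholds) {
  es <- thresholds$energy_share
  sugar <- ifelse(declared, free_fraction * sh$sugar >= es$free_sugar, NA)
  cbind(
    free_sugar = sugar,
    total_fat = sh$fat >= es$total_fat,
    sat_fat = sh$sat >= es$sat_fat,
    trans_fat = sh$trans >= es$trans_fat,
    sodium = sh$sodium >= thresholds$sodium_mg_per_kcal
  )
}

#' @keywords internal
draw_shares <- function(params, idx) {
  n <- length(idx)
  fat <- rlnorm(n, params$fat_meanlog[idx], params$fat_sdlog[idx])
  sat <- pmin(rlnorm(n, params$sat_meanlog[idx], params$sat_sdlog[idx]), fat)
  trans <- pmin(rlnorm(n, params$trans_meanlog[idx], params$trans_sdlog[idx]), fat)
  list(
    sugar = rlnorm(n, params$sugar_meanlog[idx], params$sugar_sdlog[idx]),
    fat = fat, sat = sat, trans = trans,
    sodium = rlnorm(n, params$sodium_meanlog[idx], params$sodium_sdlog[idx])
  )
}

#' @keywords internal
draw_additions <- function(params, idx) {
  n <- length(idx)
  list(
    sugar = runif(n) < params$p_add_sugar[idx],
    salt = runif(n) < params$p_add_salt[idx],
    fat = runif(n) < params$p_add_fat[idx],
    nns = runif(n) < params$p_nns[idx]
  )
}

#' Generate a synthetic packaged-food supply with ground truth
#'
#' Emulates the statistical structure of a packaged-food label dataset:
#' category mix, per-category nutrient-to-energy distributions, ingredient
#' lists with planted keywords (plus distractor tokens including
#' false-positive traps such as "salsa"), front-of-package claim segments
#' realized from the claim pattern lexicon, a configurable total-sugar
#' declaration rate, and a planted association between nutrition-claim
#' presence and high-in-any status. High-in status is induced by redrawing
#' panels conditional on the claim assignment (up to `max_redraws` rounds)
#' with a deterministic construction forcing the residual mismatches, so
#' the planted conditional proportions hold exactly in expectation.
#'
#' Ground truth is returned separately from the product table; the
#' analysis path consumes only the products.
#'
#' @param config A [generator_config()].
#' @param thresholds Threshold configuration the truth is computed under.
#' @param fraction_map Free-sugar fraction map.
#' @param ingredient_lexicon,claim_lexicon Lexicons used to realize texts.
#' @return List with `products` (a valid product tibble) and `truth`
#'   (tibble: planted addition flags, declaration status, claim indicators
#'   and per-segment labels, excess flags and `high_in_any`).
#' @export
generate_products <- function(config,
                              thresholds = default_thresholds(),
                              fraction_map = default_fraction_map(),
                              ingredient_lexicon = default_ingredient_lexicon(),
                              claim_lexicon = default_claim_lexicon()) {
  stopifnot(inherits(config, "fop_generator_config"))
  set.seed(config$seed)
  n <- config$n
  cats <- fop_categories()
  if (n == 0) {
    return(list(
      products = empty_products(),
      truth = tibble::tibble(product_id = character(0))
    ))
  }
  params <- config$params
  idx <- sample.int(25, n, replace = TRUE, prob = config$category_weights)
  category <- cats[idx]

  ## --- claims -------------------------------------------------------------
  any_claim <- runif(n) < config$p_any_cat[idx]
  majors <- matrix(FALSE, n, 3,
    dimnames = list(NULL, c("health", "nutrition", "environment"))
  )
  claimers <- which(any_claim)
  if (length(claimers) > 0) {
    q <- config$q_major[c("health", "nutrition", "environment")]
    m <- length(claimers)
    draw <- matrix(runif(3 * m), m, 3) < rep(q, each = m)
    empty <- rowSums(draw) == 0
    while (any(empty)) {
      k <- sum(empty)
      draw[empty, ] <- matrix(runif(3 * k), k, 3) < rep(q, each = k)
      empty <- rowSums(draw) == 0
    }
    majors[claimers, ] <- draw
  }
  seg_sub <- list()
  seg_text <- list()
  for (mj in c("health", "nutrition", "environment")) {
    present <- which(majors[, mj])
    sub <- rep(NA_character_, n)
    txt <- rep(NA_character_, n)
    if (length(present) > 0) {
      dist <- config$sub_dist[[mj]]
      sub[present] <- sample(names(dist), length(present),
        replace = TRUE, prob = dist
      )
      for (sb in unique(sub[present])) {
        rows <- present[sub[present] == sb]
        pats <- claim_lexicon$pattern[
          claim_lexicon$major == mj & claim_lexicon$sub == sb
        ]
        txt[rows] <- sample(pats, length(rows), replace = TRUE)
      }
      if (config$noisy_text_rate > 0) {
        noisy <- present[runif(length(present)) < config$noisy_text_rate]
        txt[noisy] <- paste("sabor incrível", seq_along(noisy))
      }
    }
    seg_sub[[mj]] <- sub
    seg_text[[mj]] <- txt
  }

  ## --- target high-in status and panel -----------------------------------
  target_high <- runif(n) < ifelse(
    majors[, "nutrition"],
    config$p_high_given_nutrition, config$p_high_given_no_nutrition
  )
  declared <- runif(n) < config$p_sugar_declared
  additions <- draw_additions(params, idx)
  shares <- draw_shares(params, idx)
  free_frac <- free_sugar_fraction(category, additions$sugar, fraction_map)
  exc <- shares_excess(shares, free_frac, declared, thresholds)
  high <- rowSums(!is.na(exc) & exc) > 0

  round_i <- 0
  while (round_i < config$max_redraws && any(high != target_high)) {
    round_i <- round_i + 1
    bad <- which(high != target_high)
    add2 <- draw_additions(params, idx[bad])
    sh2 <- draw_shares(params, idx[bad])
    for (nm in names(additions)) additions[[nm]][bad] <- add2[[nm]]
    for (nm in names(shares)) shares[[nm]][bad] <- sh2[[nm]]
    free_frac <- free_sugar_fraction(category, additions$sugar, fraction_map)
    exc <- shares_excess(shares, free_frac, declared, thresholds)
    high <- rowSums(!is.na(exc) & exc) > 0
  }
  force_high <- which(!high & target_high)
  if (length(force_high) > 0) {
    shares$sodium[force_high] <-
      thresholds$sodium_mg_per_kcal * runif(length(force_high), 1.5, 3)
    additions$salt[force_high] <- TRUE
  }
  force_low <- which(high & !target_high)
  if (length(force_low) > 0) {
    m <- length(force_low)
    u <- function() runif(m, 0.1, 0.85)
    es <- thresholds$energy_share
    shares$sugar[force_low] <- es$free_sugar * u()
    shares$fat[force_low] <- es$total_fat * u()
    shares$sat[force_low] <- pmin(es$sat_fat * u(), shares$fat[force_low])
    shares$trans[force_low] <- pmin(es$trans_fat * u(), shares$fat[force_low])
    shares$sodium[force_low] <- thresholds$sodium_mg_per_kcal * u()
  }
  free_frac <- free_sugar_fraction(category, additions$sugar, fraction_map)
  exc <- shares_excess(shares, free_frac, declared, thresholds)
  high <- rowSums(!is.na(exc) & exc) > 0

  ## --- assemble panel ----------------------------------------------------
  energy100 <- rlnorm(n, params$energy_meanlog[idx], params$energy_sdlog[idx])
  basis <- sample(c(100, 200, 30), n, replace = TRUE, prob = c(.7, .15, .15))
  scale <- basis / 100
  energy <- energy100 * scale
  panel <- tibble::tibble(
    energy_kcal = energy,
    total_sugars_g = ifelse(declared, shares$sugar * energy / thresholds$kcal_per_g$sugar, NA_real_),
    total_fat_g = shares$fat * energy / thresholds$kcal_per_g$fat,
    saturated_fat_g = shares$sat * energy / thresholds$kcal_per_g$fat,
    trans_fat_g = shares$trans * energy / thresholds$kcal_per_g$fat,
    sodium_mg = shares$sodium * energy,
    basis_amount = basis
  )

  ## --- ingredient text ---------------------------------------------------
  pool <- generator_distractors()
  d <- matrix(sample(pool, 3 * n, replace = TRUE), n, 3)
  ing <- paste(d[, 1], d[, 2], d[, 3], sep = ", ")
  add_kw <- function(ing, flag, set) {
    kw <- sample(ingredient_lexicon[[set]], n, replace = TRUE)
    ifelse(flag, paste(ing, kw, sep = ", "), ing)
  }
  ing <- add_kw(ing, additions$sugar, "sugar")
  ing <- add_kw(ing, additions$salt, "salt")
  ing <- add_kw(ing, additions$fat, "fat")
  ing <- add_kw(ing, additions$nns, "nns")

  ## --- front-of-package segments -----------------------------------------
  th <- seg_text$health
  tn <- seg_text$nutrition
  te <- seg_text$environment
  fop <- lapply(seq_len(n), function(i) {
    s <- c(th[i], tn[i], te[i])
    s[!is.na(s)]
  })

  product_id <- sprintf("P%06d", seq_len(n))
  products <- tibble::tibble(
    product_id = product_id, category = category,
    energy_kcal = panel$energy_kcal, total_sugars_g = panel$total_sugars_g,
    total_fat_g = panel$total_fat_g, saturated_fat_g = panel$saturated_fat_g,
    trans_fat_g = panel$trans_fat_g, sodium_mg = panel$sodium_mg,
    basis_amount = panel$basis_amount, ingredients_text = ing,
    fop_texts = fop, is_culinary = default_is_culinary(category)
  )
  truth <- tibble::tibble(
    product_id = product_id, category = category,
    added_sugar = additions$sugar, added_salt = additions$salt,
    added_fat = additions$fat, nns = additions$nns,
    sugars_declared = declared,
    claim_any = any_claim,
    claim_health = majors[, "health"],
    claim_nutrition = majors[, "nutrition"],
    claim_environment = majors[, "environment"],
    health_sub = seg_sub$health, nutrition_sub = seg_sub$nutrition,
    environment_sub = seg_sub$environment,
    excess_free_sugar = exc[, "free_sugar"],
    excess_total_fat = exc[, "total_fat"],
    excess_sat_fat = exc[, "sat_fat"],
    excess_trans_fat = exc[, "trans_fat"],
    excess_sodium = exc[, "sodium"],
    high_in_any = high
  )
  list(products = products, truth = truth)
}

#' Configured vs analytically implied generator marginals
#'
#' Closed-form marginals implied by a generator configuration (mixtures
#' over categories and the conditional claim allocation), for verifying a
#' configuration against published values before simulating.
#'
#' @param config A [generator_config()].
#' @return Tibble: `quantity`, `configured`, `implied`.
#' @export
calibration_report <- function(config) {
  stopifnot(inherits(config, "fop_generator_config"))
  w <- config$category_weights
  implied_any <- sum(w * config$p_any_cat)
  q <- config$q_major
  p_cond <- q / (1 - prod(1 - q))
  implied_major <- implied_any * p_cond
  p_nut <- implied_major[["nutrition"]]
  implied_high <- p_nut * config$p_high_given_nutrition +
    (1 - p_nut) * config$p_high_given_no_nutrition
  tibble::tibble(
    quantity = c(
      "claim_any", "claim_health", "claim_nutrition", "claim_environment",
      "sugar_declared", "high_in_any"
    ),
    configured = c(
      config$p_any_claim, config$p_major[["health"]],
      config$p_major[["nutrition"]], config$p_major[["environment"]],
      config$p_sugar_declared, NA_real_
    ),
    implied = c(
      implied_any, implied_major[["health"]], implied_major[["nutrition"]],
      implied_major[["environment"]], config$p_sugar_declared, implied_high
    )
  )
}
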