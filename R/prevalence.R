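#' Binomial proportion with confidence interval
#'
#' Default interval is the Wilson score interval, chosen for its behaviour
#' at the boundaries (k = 0 still yields a positive upper limit; k = n a
#' lower limit below 1). A Clopper-Pearson exact interval is available via
#' `method = "exact"`. The method used is recorded in every output row so
#' alternatives can be swapped through configuration.
#'
#' @param k Numerator (successes). Vectorized.
#' @param n Denominator (trials). Vectorized, all >= 1.
#' @param level Confidence level (default 0.95).
#' @param method `"wilson"` (default) or `"exact"`.
#' @return Tibble with `k`, `n`, `p`, `lo`, `hi`, `level`, `method`.
#' @export
#' @examples
#' prevalence_ci(c(0, 5, 10), 10)
prevalence_ci <- function(k, n, level = 0.95, method = c("wilson", "exact")) {
  method <- match.arg(method)
  if (length(n) == 1) n <- rep(n, length(k))
  stopifnot(length(k) == length(n))
  if (any(n < 1)) stop("prevalence_ci: denominator must be >= 1", call. = FALSE)
  if (any(k < 0 | k > n)) {
    stop("prevalence_ci: need 0 <= k <= n", call. = FALSE)
  }
  p <- k / n
  alpha <- 1 - level
  if (method == "wilson") {
    z <- qnorm(1 - alpha / 2)
    denom <- 1 + z^2 / n
    center <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- pmax(0, center - half)
    hi <- pmin(1, center + half)
  } else {
    lo <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n - k + 1))
    hi <- ifelse(k == n, 1, stats::qbeta(1 - alpha / 2, k + 1, n - k))
  }
  tibble::tibble(k = k, n = n, p = p, lo = lo, hi = hi,
                 level = level, method = method)
}

#' Claim prevalence by food category
#'
#' Prevalence of front-of-package claims — any, and per major category —
#' for each of the 25 food categories and overall, with confidence
#' intervals. Categories with no products are emitted with `n = 0` and `NA`
#' prevalence rather than dropped. The overall row's numerators equal the
#' sum over categories.
#'
#' @param products A product table.
#' @param annotations Per-product claim indicators
#'   ([annotate_product_claims()]).
#' @param claim_cols Indicator columns to tabulate (default: any plus the
#'   three majors).
#' @param level,method Passed to [prevalence_ci()].
#' @return Long tibble: `category`, `claim_type`, `k`, `n`, `p`, `lo`,
#'   `hi`, `level`, `method`.
#' @export
claim_prevalence_table <- function(products, annotations,
                                   claim_cols = c(
                                     "claim_any", "claim_health",
                                     "claim_nutrition", "claim_environment"
                                   ),
                                   level = 0.95, method = "wilson") {
  products <- as_product_table(products)
  dat <- dplyr::inner_join(
    products[, c("product_id", "category")], annotations,
    by = "product_id"
  )
  cats <- c(fop_categories(), "Overall")
  rows <- lapply(cats, function(ct) {
    sub <- if (ct == "Overall") dat else dat[dat$category == ct, , drop = FALSE]
    n <- nrow(sub)
    out <- lapply(claim_cols, function(cl) {
      k <- sum(sub[[cl]])
      if (n == 0) {
        tibble::tibble(
          category = ct, claim_type = cl, k = 0L, n = 0L,
          p = NA_real_, lo = NA_real_, hi = NA_real_,
          level = level, method = method
        )
      } else {
        ci <- prevalence_ci(k, n, level, method)
        dplyr::bind_cols(tibble::tibble(category = ct, claim_type = cl), ci)
      }
    })
    dplyr::bind_rows(out)
  })
  dplyr::bind_rows(rows)
}

#' High-in-critical-nutrient prevalence by claim presence
#'
#' For each claim type (and optionally each stratum), the proportion of
#' products high in any critical nutrient among products *with* the claim
#' and among products *without* it, each with its confidence interval, plus
#' an indicator of whether the two intervals fail to overlap — the
#' comparison device of the analysis plan (CI comparison, no hypothesis
#' test, no multiplicity correction).
#'
#' @param annotations Per-product claim indicators.
#' @param profiles Warning profiles ([profile_products()]), joined by
#'   `product_id`.
#' @param stratify `"none"` for the overall comparison or `"category"` for
#'   the per-food-category tables.
#' @param claim_cols Indicator columns to compare (default: the three
#'   majors plus every subcategory).
#' @param level,method Passed to [prevalence_ci()].
#' @return Tibble: `stratum`, `claim_type`, then for each arm (`yes`/`no`)
#'   `k`, `n`, `p`, `lo`, `hi`, and `ci_nonoverlap` (NA when an arm is
#'   empty).
#' @export
warning_by_claim_table <- function(annotations, profiles,
                                   stratify = c("none", "category"),
                                   claim_cols = NULL,
                                   level = 0.95, method = "wilson") {
  stratify <- match.arg(stratify)
  if (is.null(claim_cols)) {
    claim_cols <- setdiff(claim_indicator_columns(), "claim_any")
  }
  missing_ids <- setdiff(annotations$product_id, profiles$product_id)
  if (length(missing_ids) > 0) {
    stop(
      "warning_by_claim_table: no profile for product id(s): ",
      paste(head(missing_ids, 5), collapse = ", "),
      if (length(missing_ids) > 5) ", ...",
      call. = FALSE
    )
  }
  dat <- dplyr::inner_join(
    annotations,
    profiles[, c("product_id", "category", "high_in_any")],
    by = "product_id"
  )
  strata <- if (stratify == "none") "Overall" else fop_categories()
  rows <- list()
  for (st in strata) {
    sub <- if (st == "Overall") dat else dat[dat$category == st, , drop = FALSE]
    for (cl in claim_cols) {
      arm <- function(mask) {
        n <- sum(mask)
        if (n == 0) {
          tibble::tibble(k = 0L, n = 0L, p = NA_real_,
                         lo = NA_real_, hi = NA_real_)
        } else {
          prevalence_ci(sum(sub$high_in_any[mask]), n, level, method)[
            , c("k", "n", "p", "lo", "hi")
          ]
        }
      }
      yes <- arm(sub[[cl]])
      no <- arm(!sub[[cl]])
      nonoverlap <- if (yes$n == 0 || no$n == 0) {
        NA
      } else {
        yes$lo > no$hi || no$lo > yes$hi
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        stratum = st, claim_type = cl,
        k_yes = yes$k, n_yes = yes$n, p_yes = yes$p,
        lo_yes = yes$lo, hi_yes = yes$hi,
        k_no = no$k, n_no = no$n, p_no = no$p,
        lo_no = no$lo, hi_no = no$hi,
        ci_nonoverlap = nonoverlap, level = level, method = method
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Claim prevalence among foods high in a given nutrient
#'
#' The appendix-style stratification: among products whose excess flag for
#' a given critical nutrient is TRUE, the prevalence of each claim type.
#'
#' @inheritParams warning_by_claim_table
#' @param nutrients Excess-nutrient strata (default: free sugars,
#'   saturated fat, sodium).
#' @return Tibble: `excess_nutrient`, `claim_type`, `k`, `n`, `p`, `lo`,
#'   `hi` (`n = 0` rows carry `NA` prevalence).
#' @export
claim_prevalence_by_excess <- function(annotations, profiles,
                                       nutrients = c(
                                         "free_sugar", "sat_fat", "sodium"
                                       ),
                                       claim_cols = c(
                                         "claim_any", "claim_health",
                                         "claim_nutrition", "claim_environment"
                                       ),
                                       level = 0.95, method = "wilson") {
  dat <- dplyr::inner_join(
    annotations,
    profiles[, c("product_id", paste0("excess_", nutrients))],
    by = "product_id"
  )
  rows <- list()
  for (nu in nutrients) {
    flag <- dat[[paste0("excess_", nu)]]
    sub <- dat[!is.na(flag) & flag, , drop = FALSE]
    for (cl in claim_cols) {
      n <- nrow(sub)
      rows[[length(rows) + 1]] <- if (n == 0) {
        tibble::tibble(
          excess_nutrient = nu, claim_type = cl, k = 0L, n = 0L,
          p = NA_real_, lo = NA_real_, hi = NA_real_,
          level = level, method = method
        )
      } else {
        dplyr::bind_cols(
          tibble::tibble(excess_nutrient = nu, claim_type = cl),
          prevalence_ci(sum(sub[[cl]]), n, level, method)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Stratified random subsample by category
#'
#' Draws, within each food category, a fixed fraction of products at
#' random (rounded to the nearest count, at least one product per
#' non-empty category), mirroring the study's 30% per-category subsampling
#' step. Uses the current RNG state: call `set.seed()` first for
#' reproducibility.
#'
#' @param products A product table.
#' @param fraction Sampling fraction in (0, 1\].
#' @return The sampled product tibble.
#' @export
sample_by_category <- function(products, fraction = 0.30) {
  stopifnot(fraction > 0, fraction <= 1)
  products <- as_product_table(products)
  idx <- unlist(lapply(split(seq_len(nrow(products)), products$category),
    function(rows) {
      size <- max(1L, round(fraction * length(rows)))
      sort(sample(rows, size))
    }
  ), use.names = FALSE)
  products[sort(idx), , drop = FALSE]
}

#' Run the full analysis
#'
#' Executes the complete pipeline in order — obtain products (from a file
#' or the synthetic generator), screen ingredients and profile nutrients,
#' classify claims, then emit the claim-prevalence table, the
#' high-in-by-claim comparison, the per-category stratified tables, the
#' excess-nutrient stratification, and (when double entries are supplied)
#' the reliability report — writing each as CSV plus a JSON run manifest.
#' With a fixed seed the outputs are byte-identical across runs.
#'
#' @param config A list:
#'   \describe{
#'     \item{seed}{integer seed (required).}
#'     \item{products}{path to a product CSV/JSON file, or a product
#'       tibble; omit to use the generator.}
#'     \item{generator}{a [generator_config()] list (used when `products`
#'       is absent).}
#'     \item{out_dir}{output directory (created if needed); omit to skip
#'       writing files.}
#'     \item{level}{confidence level (default 0.95).}
#'     \item{ci_method}{"wilson" (default) or "exact".}
#'     \item{double_entries}{optional named list for [agreement_report()].}
#'   }
#' @return (Invisibly) a list with `products`, `profiles`, `annotations`,
#'   `claim_prevalence`, `warning_by_claim`, `warning_by_claim_category`,
#'   `claims_by_excess`, `reliability` (or NULL), and `manifest`.
#' @export
run_full_analysis <- function(config) {
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  level <- config$level %||% 0.95
  ci_method <- config$ci_method %||% "wilson"
  set.seed(config$seed)

  if (!is.null(config$products)) {
    products <- if (is.character(config$products)) {
      fmt <- if (grepl("\\.json[l]?$", config$products)) "json" else "csv"
      read_products(config$products, fmt, quiet = TRUE)
    } else {
      validate_products(config$products, quiet = TRUE)
    }
    source_desc <- "supplied product table"
  } else {
    gc_cfg <- do.call(generator_config, c(
      config$generator %||% list(),
      if (is.null((config$generator %||% list())$seed)) list(seed = config$seed)
    ))
    if (gc_cfg$n == 0) {
      stop("run_full_analysis: generator n must be positive", call. = FALSE)
    }
    gen <- generate_products(gc_cfg)
    products <- gen$products
    source_desc <- sprintf("synthetic generator (n=%d)", gc_cfg$n)
  }

  profiles <- profile_products(products)
  annotations <- annotate_product_claims(products)
  fig1 <- claim_prevalence_table(products, annotations,
    level = level, method = ci_method
  )
  fig2 <- warning_by_claim_table(annotations, profiles,
    stratify = "none",
    claim_cols = c("claim_health", "claim_nutrition", "claim_environment"),
    level = level, method = ci_method
  )
  tables <- warning_by_claim_table(annotations, profiles,
    stratify = "category", level = level, method = ci_method
  )
  appendix <- claim_prevalence_by_excess(annotations, profiles,
    level = level, method = ci_method
  )
  reliability <- if (!is.null(config$double_entries)) {
    agreement_report(config$double_entries)
  } else {
    NULL
  }

  manifest <- list(
    package = "foplabel",
    package_version = as.character(utils::packageVersion("foplabel")),
    seed = config$seed,
    source = source_desc,
    n_products = nrow(products),
    level = level,
    ci_method = ci_method,
    ingredient_lexicon_version = default_ingredient_lexicon()$version,
    claim_lexicon_version = attr(default_claim_lexicon(), "version"),
    config_hash = config_hash(config)
  )

  out <- list(
    products = products, profiles = profiles, annotations = annotations,
    claim_prevalence = fig1, warning_by_claim = fig2,
    warning_by_claim_category = tables, claims_by_excess = appendix,
    reliability = reliability, manifest = manifest
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name) {
      readr::write_csv(df, file.path(config$out_dir, name), progress = FALSE)
    }
    w(fig1, "claim_prevalence_by_category.csv")
    w(fig2, "high_in_by_claim_overall.csv")
    w(tables, "high_in_by_claim_by_category.csv")
    w(appendix, "claims_among_high_in.csv")
    if (!is.null(reliability)) w(reliability, "reliability_report.csv")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(out)
}

#' @keywords internal
config_hash <- function(config) {
  cfg <- config[setdiff(names(config), c("out_dir", "double_entries", "products"))]
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(
    jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE), tmp
  )
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
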