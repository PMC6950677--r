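#' Claim taxonomy constants
#'
#' The taxonomy's three major claim categories (plus `none`) and the
#' subcategories of each major, in classification-precedence order.
#'
#' @return `claim_majors()`: the majors in hierarchy order (health >
#'   nutrition > environment). `claim_subcategories()`: named list of
#'   subcategory vectors in within-major precedence order.
#' @export
claim_majors <- function() c("health", "nutrition", "environment")

#' @rdname claim_majors
#' @export
claim_subcategories <- function() {
  list(
    health = c("special_diets", "natural", "general", "others"),
    nutrition = c("of_concern", "not_of_concern", "others"),
    environment = "environment"
  )
}

#' Front-of-package claim pattern lexicon
#'
#' Loads a claim pattern lexicon: one set of Portuguese text patterns per
#' (major, subcategory) cell of the claim taxonomy. The default ships as an
#' editable YAML file
#' (`system.file("extdata", "claim_lexicon.yml", package = "foplabel")`).
#'
#' @param path Path to a claim-lexicon YAML file.
#' @return Tibble with columns `major`, `sub`, `pattern`, and the file's
#'   `version` in attribute `"version"`.
#' @export
read_claim_lexicon <- function(path) {
  raw <- yaml::read_yaml(path)
  subs <- claim_subcategories()
  rows <- list()
  for (mj in claim_majors()) {
    if (is.null(raw[[mj]])) {
      stop("claim lexicon lacks major category '", mj, "': ", path,
        call. = FALSE
      )
    }
    for (sb in subs[[mj]]) {
      pats <- as.character(unlist(raw[[mj]][[sb]]))
      if (length(pats) == 0) {
        stop(
          "claim lexicon cell ", mj, "/", sb, " has no patterns: ", path,
          call. = FALSE
        )
      }
      rows[[length(rows) + 1]] <-
        tibble::tibble(major = mj, sub = sb, pattern = pats)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "version") <- raw$version
  out
}

#' @rdname read_claim_lexicon
#' @export
default_claim_lexicon <- function() {
  read_claim_lexicon(
    system.file("extdata", "claim_lexicon.yml",
      package = "foplabel", mustWork = TRUE
    )
  )
}

#' Classify front-of-package text segments
#'
#' Assigns each segment exactly one (major, subcategory) cell, or
#' `major = "none"` when no pattern matches. Patterns match as contiguous
#' token runs after lowercasing and accent folding. When patterns from
#' several major categories match the same segment, the classification
#' hierarchy applies: health > nutrition > environment. Within health,
#' subcategory precedence is special diets > natural > general > others;
#' within nutrition, nutrients of concern > not of concern > others.
#'
#' Only front-of-package segments should be passed: ingredient-list
#' mentions and mandatory panel text are not claims.
#'
#' @param texts Character vector of segments.
#' @param lexicon Claim lexicon ([default_claim_lexicon()]).
#' @return Tibble with columns `text`, `major` (`"health"`, `"nutrition"`,
#'   `"environment"` or `"none"`) and `sub` (`NA` when `major` is none).
#' @export
#' @examples
#' classify_claim(c("orgânico", "fonte de fibras", "bom dia"))
classify_claim <- function(texts, lexicon = default_claim_lexicon()) {
  texts <- as.character(texts)
  padded <- token_string(texts)
  needles <- token_string(lexicon$pattern)
  hit <- vapply(
    needles, function(nd) grepl(nd, padded, fixed = TRUE),
    logical(length(texts))
  )
  if (length(texts) == 1) hit <- matrix(hit, nrow = 1)
  major <- rep("none", length(texts))
  sub <- rep(NA_character_, length(texts))
  subs <- claim_subcategories()
  for (mj in claim_majors()) {
    for (sb in subs[[mj]]) {
      cell <- lexicon$major == mj & lexicon$sub == sb
      cell_hit <- rowSums(hit[, cell, drop = FALSE]) > 0
      take <- major == "none" & cell_hit
      major[take] <- mj
      sub[take] <- sb
    }
  }
  tibble::tibble(text = texts, major = major, sub = sub)
}

#' Is a nutrient tag "of concern"?
#'
#' Nutrients of concern are those whose excess intake is associated with
#' increased non-communicable disease risk: saturated fat, trans fat,
#' sugar, and sodium. The remaining controlled vocabulary (fiber, vitamins,
#' minerals, unsaturated fat, protein) is not of concern.
#'
#' @param nutrient_tag Character vector of tags.
#' @return Logical vector; unknown tags raise an error.
#' @export
is_nutrient_of_concern <- function(nutrient_tag) {
  of_concern <- c("saturated_fat", "trans_fat", "sugar", "sodium")
  not_of_concern <- c("fiber", "vitamins", "minerals", "unsaturated_fat", "protein")
  unknown <- !(nutrient_tag %in% c(of_concern, not_of_concern))
  if (any(unknown)) {
    stop(
      "unknown nutrient tag(s): ",
      paste(unique(nutrient_tag[unknown]), collapse = ", "),
      call. = FALSE
    )
  }
  nutrient_tag %in% of_concern
}

#' @keywords internal
claim_indicator_columns <- function() {
  subs <- claim_subcategories()
  c(
    "claim_any", paste0("claim_", claim_majors()),
    unlist(lapply(claim_majors(), function(mj) paste0(mj, "_", subs[[mj]])),
      use.names = FALSE
    )
  )
}

#' Per-product claim presence indicators
#'
#' Classifies every front-of-package segment of every product and
#' aggregates to per-product booleans: one per major category and one per
#' (major, subcategory) cell, OR-ed over the product's segments. Claim
#' types are not mutually exclusive at product level — a product may carry
#' several. Only `fop_texts` is scanned; ingredient text never enters.
#'
#' @param products A product table.
#' @param lexicon Claim lexicon.
#' @return Tibble: `product_id`, `claim_any`, `claim_health`,
#'   `claim_nutrition`, `claim_environment`, and one column per
#'   subcategory (`health_general`, …, `environment_environment`).
#' @export
annotate_product_claims <- function(products,
                                    lexicon = default_claim_lexicon()) {
  products <- as_product_table(products)
  n_seg <- lengths(products$fop_texts)
  seg_owner <- rep.int(seq_len(nrow(products)), n_seg)
  segments <- unlist(products$fop_texts, use.names = FALSE)
  ann <- if (length(segments) > 0) {
    classify_claim(segments, lexicon)
  } else {
    tibble::tibble(text = character(0), major = character(0), sub = character(0))
  }
  coded <- tibble::tibble(
    product_id = products$product_id[seg_owner],
    major = ann$major, sub = ann$sub
  )
  annotate_coded_claims(coded, product_ids = products$product_id)
}

#' Aggregate pre-coded claim labels to product indicators
#'
#' Coded-input mode: takes segment-level (major, sub) labels — e.g. from
#' manual coding — and produces the same per-product indicator table as
#' [annotate_product_claims()], bypassing the pattern lexicon.
#'
#' @param coded Tibble with columns `product_id`, `major`, `sub` (one row
#'   per coded segment; `major = "none"` rows are ignored).
#' @param product_ids Full vector of product ids defining the output rows
#'   (products without segments get all-FALSE indicators); defaults to the
#'   ids present in `coded`.
#' @return Same shape as [annotate_product_claims()].
#' @export
annotate_coded_claims <- function(coded, product_ids = unique(coded$product_id)) {
  subs <- claim_subcategories()
  out <- tibble::tibble(product_id = as.character(product_ids))
  for (col in claim_indicator_columns()) out[[col]] <- FALSE
  active <- coded[!is.na(coded$major) & coded$major != "none", , drop = FALSE]
  if (nrow(active) > 0) {
    bad_major <- !(active$major %in% claim_majors())
    if (any(bad_major)) {
      stop(
        "unknown claim major(s): ",
        paste(unique(active$major[bad_major]), collapse = ", "),
        call. = FALSE
      )
    }
    idx <- match(active$product_id, out$product_id)
    if (anyNA(idx)) {
      stop("coded claims reference unknown product ids", call. = FALSE)
    }
    for (mj in claim_majors()) {
      rows <- idx[active$major == mj]
      out[[paste0("claim_", mj)]][rows] <- TRUE
      for (sb in subs[[mj]]) {
        rows_sb <- idx[active$major == mj & active$sub == sb]
        out[[paste0(mj, "_", sb)]][rows_sb] <- TRUE
      }
    }
    out$claim_any <- out$claim_health | out$claim_nutrition | out$claim_environment
  }
  out
}
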