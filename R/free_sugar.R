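#' Free-sugar fraction map
#'
#' Free sugars are not declared on Brazilian nutrition facts panels; they
#' are estimated as a category-specific fraction of declared total sugars,
#' using exactly four fraction levels: 0, 0.50, 0.75 and 1.00. The default
#' map is a reconstruction (the source NPM names only the boundary cases —
#' all sugars free for beverages with no intrinsic sugars such as soda, and
#' 50% for milk/yogurt with a sugar keyword in the ingredient list) and
#' ships as an editable YAML file
#' (`system.file("extdata", "free_sugar_fractions.yml", package = "foplabel")`).
#'
#' Each product category maps to one estimation class:
#' \describe{
#'   \item{all_free}{no intrinsic sugars; fraction 1.00 regardless of the
#'     added-sugar flag (soda, fruit-flavored drinks, table sugar, candies).}
#'   \item{dairy}{fraction 0.50 when a sugar keyword is present, else 0.}
#'   \item{fruit_based}{added and intrinsic sugars mixed; 0.75 with a sugar
#'     keyword, else 0 (nectars, juices, fruit preserves).}
#'   \item{intrinsic_only}{fraction 0 always (packaged produce, plain
#'     meats/eggs).}
#'   \item{added_when_flagged}{negligible intrinsic sugars; 1.00 with a
#'     sugar keyword, else 0 (grain products, snacks, sauces, ...).}
#' }
#'
#' @param path Path to a fraction-map YAML file.
#' @return A fraction map: list with `version`, `fractions` (named numeric,
#'   the four levels), and `classes` (named list: class → character vector
#'   of categories).
#' @export
read_fraction_map <- function(path) {
  fm <- yaml::read_yaml(path)
  if (is.null(fm$classes) || is.null(fm$fractions)) {
    stop("fraction map file needs 'classes' and 'fractions' keys: ", path,
      call. = FALSE
    )
  }
  fm$classes <- lapply(fm$classes, function(x) as.character(unlist(x)))
  fm
}

#' @rdname read_fraction_map
#' @export
default_fraction_map <- function() {
  read_fraction_map(
    system.file("extdata", "free_sugar_fractions.yml",
      package = "foplabel", mustWork = TRUE
    )
  )
}

#' @keywords internal
fraction_class_of <- function(category, fraction_map) {
  category <- as.character(category)
  cls <- rep(NA_character_, length(category))
  for (nm in names(fraction_map$classes)) {
    cls[category %in% fraction_map$classes[[nm]]] <- nm
  }
  if (anyNA(cls)) {
    stop(
      "no free-sugar estimation class configured for category: ",
      paste(unique(category[is.na(cls)]), collapse = ", "),
      call. = FALSE
    )
  }
  cls
}

#' Applied free-sugar fraction for a category
#'
#' @param category Character vector of category labels.
#' @param added_sugar Logical vector: sugar keyword found in the ingredient
#'   list.
#' @param fraction_map A fraction map ([default_fraction_map()]).
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
free_sugar_fraction <- function(category, added_sugar,
                                fraction_map = default_fraction_map()) {
  cls <- fraction_class_of(category, fraction_map)
  fr <- fraction_map$fractions
  out <- numeric(length(cls))
  out[cls == "all_free"] <- fr[["full"]]
  out[cls == "dairy"] <- ifelse(added_sugar[cls == "dairy"], fr[["half"]], 0)
  out[cls == "fruit_based"] <-
    ifelse(added_sugar[cls == "fruit_based"], fr[["three_quarters"]], 0)
  out[cls == "intrinsic_only"] <- fr[["none"]]
  out[cls == "added_when_flagged"] <-
    ifelse(added_sugar[cls == "added_when_flagged"], fr[["full"]], 0)
  out
}

#' Estimate free sugars from declared total sugars
#'
#' Returns `fraction × total_sugars` where the fraction is looked up from
#' the product category and the added-sugar flag. When total sugars are not
#' declared (`NA`), the estimate is `NA` — never imputed: products without
#' declared sugars contribute to no sugar-excess decision downstream.
#'
#' @param total_sugars_g Declared total sugars, g (NA when not declared).
#' @inheritParams free_sugar_fraction
#' @return Numeric vector of estimated free sugars in g; `NA` where sugars
#'   were not declared. Always within \[0, total_sugars\].
#' @export
#' @examples
#' estimate_free_sugars(10, "Soda", added_sugar = FALSE)           # 10
#' estimate_free_sugars(12, "Sweetened Dairy Products", TRUE)      # 6
estimate_free_sugars <- function(total_sugars_g, category, added_sugar,
                                 fraction_map = default_fraction_map()) {
  f <- free_sugar_fraction(category, added_sugar, fraction_map)
  f * total_sugars_g
}

#' Proportion of products declaring total sugars
#'
#' Total-sugar declaration is voluntary on Brazilian panels; analyses that
#' involve free sugars are restricted to the declaring subsample.
#'
#' @param products A product table.
#' @return Tibble with `n`, `n_declared`, `proportion`.
#' @export
free_sugar_coverage <- function(products) {
  products <- as_product_table(products)
  if (nrow(products) == 0) {
    stop("free_sugar_coverage: empty product table", call. = FALSE)
  }
  k <- sum(!is.na(products$total_sugars_g))
  tibble::tibble(
    n = nrow(products), n_declared = k, proportion = k / nrow(products)
  )
}
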