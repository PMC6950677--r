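#' @keywords internal
product_columns <- function() {
  c(
    "product_id", "category", "energy_kcal", "total_sugars_g", "total_fat_g",
    "saturated_fat_g", "trans_fat_g", "sodium_mg", "basis_amount",
    "ingredients_text", "fop_texts", "is_culinary"
  )
}

#' Construct a single product record
#'
#' Convenience constructor returning a one-row product table in the schema
#' shared by the whole package. Nutrient amounts are as declared on the
#' nutrition facts panel, per `basis_amount` grams (or mL) of product; the
#' profile model works on nutrient-to-energy ratios, so the declared basis
#' never needs rescaling. A missing `total_sugars_g` means sugars were not
#' declared (not zero); it is preserved as `NA` throughout.
#'
#' @param product_id Identifier (character).
#' @param category One of [fop_categories()].
#' @param energy_kcal Energy, kcal per basis amount. Must be positive for a
#'   product to be evaluable by the profile engine.
#' @param total_sugars_g Declared total sugars, g per basis, or `NA` when the
#'   panel does not declare sugars.
#' @param total_fat_g,saturated_fat_g,trans_fat_g Fats, g per basis.
#' @param sodium_mg Sodium, mg per basis.
#' @param basis_amount Declared reference amount (g or mL).
#' @param ingredients_text Ingredient list, free Portuguese text.
#' @param fop_texts Character vector of front-of-package text segments.
#' @param is_culinary Logical; defaults from the category
#'   ([default_is_culinary()]).
#' @return A one-row tibble in the product schema (`fop_texts` is a
#'   list-column).
#' @export
#' @examples
#' product_record("p1", "Soda", energy_kcal = 42, total_sugars_g = 10.6,
#'                sodium_mg = 12, ingredients_text = "água gaseificada, açúcar")
product_record <- function(product_id, category,
                           energy_kcal = NA_real_,
                           total_sugars_g = NA_real_,
                           total_fat_g = 0, saturated_fat_g = 0,
                           trans_fat_g = 0, sodium_mg = 0,
                           basis_amount = 100,
                           ingredients_text = "",
                           fop_texts = character(0),
                           is_culinary = NULL) {
  if (is.null(is_culinary)) is_culinary <- default_is_culinary(category)
  tibble::tibble(
    product_id = as.character(product_id),
    category = as.character(category),
    energy_kcal = as.numeric(energy_kcal),
    total_sugars_g = as.numeric(total_sugars_g),
    total_fat_g = as.numeric(total_fat_g),
    saturated_fat_g = as.numeric(saturated_fat_g),
    trans_fat_g = as.numeric(trans_fat_g),
    sodium_mg = as.numeric(sodium_mg),
    basis_amount = as.numeric(basis_amount),
    ingredients_text = as.character(ingredients_text),
    fop_texts = list(as.character(fop_texts)),
    is_culinary = as.logical(is_culinary)
  )
}

#' Validate a product table
#'
#' Checks every row against the product invariants: known category, no
#' negative nutrient amounts, positive basis amount. Rows failing these are
#' rejected with a row-level diagnostic. A missing or non-positive energy
#' does not reject the row: the record is kept and will come out of the
#' profile engine as not evaluable (the study design excludes such products
#' from profiling rather than dropping them from the table).
#'
#' @param products A data frame in the product schema.
#' @param quiet Suppress the accepted/rejected count message.
#' @return The accepted rows (tibble), with a tibble of rejections (columns
#'   `row`, `product_id`, `reason`) in attribute `"rejected"`.
#' @export
validate_products <- function(products, quiet = FALSE) {
  products <- as_product_table(products)
  n <- nrow(products)
  reasons <- rep(NA_character_, n)
  bad_cat <- !(products$category %in% fop_categories())
  reasons[bad_cat] <- paste0("unknown category '", products$category[bad_cat], "'")
  num_cols <- c(
    "total_sugars_g", "total_fat_g", "saturated_fat_g",
    "trans_fat_g", "sodium_mg"
  )
  for (cl in num_cols) {
    neg <- !is.na(products[[cl]]) & products[[cl]] < 0
    reasons[neg & is.na(reasons)] <- paste0("negative ", cl)
  }
  for (cl in num_cols[-1]) {
    miss <- is.na(products[[cl]])
    reasons[miss & is.na(reasons)] <- paste0("missing ", cl)
  }
  bad_basis <- is.na(products$basis_amount) | products$basis_amount <= 0
  reasons[bad_basis & is.na(reasons)] <- "missing or non-positive basis_amount"
  bad_energy <- !is.na(products$energy_kcal) & products$energy_kcal < 0
  reasons[bad_energy & is.na(reasons)] <- "negative energy_kcal"

  keep <- is.na(reasons)
  rejected <- tibble::tibble(
    row = which(!keep),
    product_id = products$product_id[!keep],
    reason = reasons[!keep]
  )
  accepted <- products[keep, , drop = FALSE]
  if (!quiet) {
    message(sprintf(
      "validate_products: %d accepted, %d rejected", nrow(accepted),
      nrow(rejected)
    ))
    if (nrow(rejected) > 0) {
      message(paste(sprintf(
        "  row %d (%s): %s", rejected$row,
        rejected$product_id, rejected$reason
      ), collapse = "\n"))
    }
  }
  attr(accepted, "rejected") <- rejected
  accepted
}

#' @keywords internal
as_product_table <- function(products) {
  products <- tibble::as_tibble(products)
  missing_cols <- setdiff(product_columns(), names(products))
  if (length(missing_cols) > 0) {
    stop(
      "product table is missing columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.list(products$fop_texts)) {
    products$fop_texts <- split_fop_texts(products$fop_texts)
  }
  products$fop_texts <- lapply(products$fop_texts, function(x) {
    as.character(unlist(x, use.names = FALSE))
  })
  if (any(is.na(products$is_culinary))) {
    idx <- is.na(products$is_culinary)
    products$is_culinary[idx] <- default_is_culinary(products$category[idx])
  }
  products[, product_columns()]
}

split_fop_texts <- function(x) {
  x <- as.character(x)
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
  })
}

join_fop_texts <- function(fop_texts) {
  vapply(fop_texts, function(seg) {
    seg <- as.character(unlist(seg, use.names = FALSE))
    if (any(grepl("|", seg, fixed = TRUE))) {
      stop("front-of-package segments must not contain '|'", call. = FALSE)
    }
    paste(seg, collapse = "|")
  }, character(1))
}

#' Read and write product tables
#'
#' `read_products()` reads a product table from CSV (UTF-8, header row, the
#' documented column order, `fop_texts` pipe-delimited, missing values as
#' empty cells) or JSON lines (one object per line, missing values as
#' `null`, `fop_texts` an array of strings), validates it with
#' [validate_products()] and returns the accepted rows. `write_products()`
#' writes the same dialects; `read_products(write_products(x))` restores `x`
#' field for field, including missing sugars.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"` (JSON lines).
#' @param quiet Passed to [validate_products()].
#' @return `read_products()`: a validated product tibble with a `"rejected"`
#'   attribute. `write_products()`: `path`, invisibly.
#' @export
read_products <- function(path, format = c("csv", "json"), quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    raw <- readr::read_csv(
      path,
      col_types = readr::cols(
        product_id = readr::col_character(),
        category = readr::col_character(),
        energy_kcal = readr::col_double(),
        total_sugars_g = readr::col_double(),
        total_fat_g = readr::col_double(),
        saturated_fat_g = readr::col_double(),
        trans_fat_g = readr::col_double(),
        sodium_mg = readr::col_double(),
        basis_amount = readr::col_double(),
        ingredients_text = readr::col_character(),
        fop_texts = readr::col_character(),
        is_culinary = readr::col_logical()
      ),
      na = "",
      progress = FALSE
    )
    raw$ingredients_text[is.na(raw$ingredients_text)] <- ""
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    rows <- lapply(lines, function(ln) {
      obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
      obj$fop_texts <- list(as.character(unlist(obj$fop_texts)))
      scalars <- setdiff(product_columns(), "fop_texts")
      for (cl in scalars) if (is.null(obj[[cl]])) obj[[cl]] <- NA
      tibble::as_tibble(obj[product_columns()])
    })
    raw <- if (length(rows) == 0) empty_products() else dplyr::bind_rows(rows)
    raw$ingredients_text[is.na(raw$ingredients_text)] <- ""
  }
  validate_products(raw, quiet = quiet)
}

#' @rdname read_products
#' @param products A validated product table.
#' @export
write_products <- function(products, path, format = c("csv", "json")) {
  format <- match.arg(format)
  products <- as_product_table(products)
  if (format == "csv") {
    flat <- products
    flat$fop_texts <- join_fop_texts(products$fop_texts)
    flat$fop_texts[!nzchar(flat$fop_texts)] <- NA_character_
    flat$ingredients_text[!nzchar(flat$ingredients_text)] <- NA_character_
    readr::write_csv(flat, path, na = "", progress = FALSE)
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(products))) {
      row <- as.list(products[i, , drop = FALSE])
      row$fop_texts <- I(row$fop_texts[[1]])
      writeLines(
        jsonlite::toJSON(row, auto_unbox = TRUE, na = "null", digits = NA),
        con
      )
    }
  }
  invisible(path)
}

#' @keywords internal
empty_products <- function() {
  product_record("x", "Soda")[0, ]
}
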