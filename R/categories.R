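#' Reporting categories for packaged foods and beverages
#'
#' The closed vocabulary of 25 food and beverage reporting categories used
#' throughout the package: by the product data model (validation), the
#' free-sugar fraction map, the synthetic generator, and every stratified
#' table. All modules share this single vector; category labels appearing
#' anywhere else must be members of it.
#'
#' @return Character vector of the 25 category labels.
#' @export
#' @examples
#' fop_categories()
fop_categories <- function() {
  c(
    "Breakfast Cereals and Granola Bars",
    "Bakery Products",
    "Convenience Foods",
    "Unsweetened Dairy Products",
    "Sweetened Dairy Products",
    "Salty Snacks",
    "Cookies",
    "Canned Vegetables",
    "Oils and Fats",
    "Sauces and Dressings",
    "Coffee and Tea",
    "Candies and Desserts",
    "Cereals, Beans, Other Grain Products",
    "Packaged Fruits and Vegetables",
    "Meat, Poultry, Seafood, and Egg",
    "Sugar and Nonnutritive Sweeteners",
    "Processed Meats",
    "Juices",
    "Nectars",
    "Fruit-Flavored Drinks",
    "Soda",
    "Other Beverages",
    "Nuts and Seeds",
    "Cheese",
    "Fruit Preserve"
  )
}

#' Culinary-ingredient categories and their identity nutrients
#'
#' Culinary ingredients (sugar, salt, oils, butter, milk creams) are basic
#' preparation items: under the modified profiling rule they can only be
#' warned for a critical nutrient added beyond their own identity. Butter is
#' the canonical case: made of milk cream and salt, it is warned for sodium
#' when sodium is in excess, but never for fats, which are its identity.
#'
#' `culinary_categories()` returns the category labels whose products are
#' culinary by default; `culinary_intrinsic_nutrients()` returns, for a
#' vector of categories, the list of critical-nutrient tags intrinsic to the
#' culinary identity of each (empty for non-culinary categories).
#'
#' @param category Character vector of category labels.
#' @return `culinary_categories()`: character vector.
#'   `culinary_intrinsic_nutrients()`: list of character vectors, one per
#'   input element, using tags `free_sugar`, `total_fat`, `sat_fat`,
#'   `trans_fat`, `sodium`.
#' @export
culinary_categories <- function() {
  c("Oils and Fats", "Sugar and Nonnutritive Sweeteners")
}

#' @rdname culinary_categories
#' @export
culinary_intrinsic_nutrients <- function(category) {
  lapply(as.character(category), function(ct) {
    switch(ct,
      "Oils and Fats" = c("total_fat", "sat_fat", "trans_fat"),
      "Sugar and Nonnutritive Sweeteners" = "free_sugar",
      character(0)
    )
  })
}

#' Default culinary flag for a category
#'
#' @param category Character vector of category labels.
#' @return Logical vector: `TRUE` for categories in [culinary_categories()].
#' @export
default_is_culinary <- function(category) {
  as.character(category) %in% culinary_categories()
}

#' Critical-nutrient tags
#'
#' The five critical nutrients of the profile model, in canonical order.
#'
#' @return Character vector of tags.
#' @export
critical_nutrients <- function() {
  c("free_sugar", "total_fat", "sat_fat", "trans_fat", "sodium")
}
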