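# Independent oracles, coded separately from the package internals.

# Accent folding by explicit codepoint lookup (distinct mechanism from the
# package's chartr-based folding).
oracle_fold <- function(x) {
  map <- c(
    "á" = "a", "à" = "a", "â" = "a", "ã" = "a", "ä" = "a",
    "é" = "e", "è" = "e", "ê" = "e", "ë" = "e",
    "í" = "i", "ì" = "i", "î" = "i", "ï" = "i",
    "ó" = "o", "ò" = "o", "ô" = "o", "õ" = "o", "ö" = "o",
    "ú" = "u", "ù" = "u", "û" = "u", "ü" = "u",
    "ç" = "c", "ñ" = "n"
  )
  vapply(x, function(s) {
    chars <- strsplit(tolower(s), "")[[1]]
    hit <- chars %in% names(map)
    chars[hit] <- map[chars[hit]]
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_tokens <- function(s) {
  toks <- strsplit(gsub("[^a-z0-9]+", " ", oracle_fold(s)), " +")[[1]]
  toks[nzchar(toks)]
}

# Brute-force token-subsequence containment: does keyword kw (possibly
# multi-word) occur as a contiguous token run in text?
oracle_contains <- function(text, kw) {
  tt <- oracle_tokens(text)
  kt <- oracle_tokens(kw)
  lk <- length(kt)
  if (lk == 0 || length(tt) < lk) return(FALSE)
  for (i in seq_len(length(tt) - lk + 1)) {
    if (all(tt[i:(i + lk - 1)] == kt)) return(TRUE)
  }
  FALSE
}

oracle_screen <- function(text, lexicon) {
  sapply(c(sugar = "sugar", salt = "salt", fat = "fat", nns = "nns"),
    function(set) any(vapply(lexicon[[set]], oracle_contains,
      logical(1), text = text
    ))
  )
}

# Ratio-comparison excess oracle: plain loop, direct arithmetic.
oracle_excess_row <- function(energy, sugars_free, fat, sat, trans, sodium, th) {
  if (is.na(energy) || energy <= 0) {
    return(rep(NA, 5))
  }
  c(
    if (is.na(sugars_free)) NA else (4 * sugars_free / energy) >= th$energy_share$free_sugar,
    (9 * fat / energy) >= th$energy_share$total_fat,
    (9 * sat / energy) >= th$energy_share$sat_fat,
    (9 * trans / energy) >= th$energy_share$trans_fat,
    (sodium / energy) >= th$sodium_mg_per_kcal
  )
}

# Eligibility / culinary truth table, a literal transcription of the rule:
# eligible iff any of added sugar/salt/fat; warnings = TRUE excess flags if
# eligible, minus the culinary identity nutrients when culinary; high-in-any
# = any TRUE excess flag regardless of eligibility.
oracle_eligibility <- function(excess5, added3, culinary, intrinsic) {
  eligible <- any(added3)
  tags <- c("free_sugar", "total_fat", "sat_fat", "trans_fat", "sodium")
  warn <- if (!eligible) character(0) else tags[!is.na(excess5) & excess5]
  if (culinary) warn <- setdiff(warn, intrinsic)
  list(
    eligible = eligible,
    warnings = warn,
    high_in_any = any(!is.na(excess5) & excess5)
  )
}

# Wilson interval oracle through stats::prop.test (no continuity correction).
oracle_wilson <- function(k, n, level = 0.95) {
  pt <- suppressWarnings(
    stats::prop.test(k, n, conf.level = level, correct = FALSE)
  )
  as.numeric(pt$conf.int)
}

# Hand-computed kappa from a confusion table.
oracle_kappa_from_table <- function(tab) {
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  (p_o - p_e) / (1 - p_e)
}

# ICC(2,1) oracle via aov() mean squares.
oracle_icc_aov <- function(a, b) {
  n <- length(a)
  d <- data.frame(
    y = c(a, b),
    item = factor(rep(seq_len(n), 2)),
    rater = factor(rep(1:2, each = n))
  )
  ms <- anova(stats::aov(y ~ item + rater, data = d))$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (2 - 1) * mse + 2 * (msc - mse) / n)
}

# Small fixture: a hand-enumerable product table.
fixture_products <- function() {
  dplyr::bind_rows(
    product_record("f1", "Soda",
      energy_kcal = 42, total_sugars_g = 10.5, sodium_mg = 10,
      ingredients_text = "água gaseificada, açúcar",
      fop_texts = "zero açúcar"
    ),
    product_record("f2", "Cookies",
      energy_kcal = 460, total_sugars_g = 30, total_fat_g = 20,
      saturated_fat_g = 9, trans_fat_g = 0.5, sodium_mg = 350,
      ingredients_text = "farinha de trigo, açúcar, gordura vegetal, sal",
      fop_texts = c("fonte de fibras", "orgânico")
    ),
    product_record("f3", "Packaged Fruits and Vegetables",
      energy_kcal = 50, total_sugars_g = 9,
      ingredients_text = "melão",
      fop_texts = character(0)
    ),
    product_record("f4", "Oils and Fats",
      energy_kcal = 720, total_fat_g = 80, saturated_fat_g = 50,
      sodium_mg = 900,
      ingredients_text = "creme de leite, sal",
      is_culinary = TRUE
    ),
    product_record("f5", "Juices",
      energy_kcal = 45, total_sugars_g = 10,
      ingredients_text = "suco de uva",
      fop_texts = "100% natural"
    ),
    product_record("f6", "Processed Meats",
      energy_kcal = 220, total_fat_g = 12, saturated_fat_g = 5,
      sodium_mg = 950,
      ingredients_text = "carne suína, sal, conservante",
      fop_texts = "fonte de proteína"
    )
  )
}
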