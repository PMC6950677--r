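#!/usr/bin/env Rscript

# Profile every simulated product under the modified nutrient profile
# model: screen the ingredient list for added sugar/salt/fat and
# nonnutritive sweeteners, estimate free sugars from declared total sugars
# by the category fraction, compare nutrient-to-energy ratios against the
# excess thresholds, and apply the eligibility and culinary rules.

suppressPackageStartupMessages(library(foplabel))

products <- read_products("results/products.csv", "csv", quiet = TRUE)
profiles <- profile_products(products)

flat <- profiles
flat$warnings <- vapply(flat$warnings, paste, character(1), collapse = ";")
readr::write_csv(flat, "results/warning_profiles.csv")

cat(sprintf(
  "Profiled %d products: %.1f%% high in any critical nutrient; %.1f%% eligible (added sugar/salt/fat); %.1f%% carry at least one warning sign.\n",
  nrow(profiles), 100 * mean(profiles$high_in_any),
  100 * mean(profiles$eligible), 100 * mean(lengths(profiles$warnings) > 0)
))
cat("Excess prevalence by nutrient (evaluable products):\n")
for (nu in critical_nutrients()) {
  fl <- profiles[[paste0("excess_", nu)]]
  cat(sprintf("  %-11s %5.1f%%  (n evaluable = %d)\n", nu,
              100 * mean(fl, na.rm = TRUE), sum(!is.na(fl))))
}
cat("Wrote results/warning_profiles.csv\n")
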