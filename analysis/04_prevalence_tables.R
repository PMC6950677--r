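#!/usr/bin/env Rscript

# The prevalence analysis: claim prevalence by category, high-in-critical-
# nutrient proportions among products with vs without each claim type
# (Wilson 95% CIs, compared by interval overlap), the per-category
# stratified tables, and the stratification of claim prevalence among
# products high in free sugars, saturated fat, and sodium.

suppressPackageStartupMessages(library(foplabel))

products <- read_products("results/products.csv", "csv", quiet = TRUE)
profiles <- profile_products(products)
annotations <- annotate_product_claims(products)

fig1 <- claim_prevalence_table(products, annotations)
fig2 <- warning_by_claim_table(annotations, profiles,
  claim_cols = c("claim_health", "claim_nutrition", "claim_environment")
)
tables <- warning_by_claim_table(annotations, profiles, stratify = "category")
appendix <- claim_prevalence_by_excess(annotations, profiles)

readr::write_csv(fig1, "results/claim_prevalence_by_category.csv")
readr::write_csv(fig2, "results/high_in_by_claim_overall.csv")
readr::write_csv(tables, "results/high_in_by_claim_by_category.csv")
readr::write_csv(appendix, "results/claims_among_high_in.csv")

ov <- fig1[fig1$category == "Overall", ]
cat("Overall claim prevalence (Wilson 95% CI):\n")
for (i in seq_len(nrow(ov))) {
  cat(sprintf(
    "  %-18s %5.1f%%  (%.1f, %.1f)\n",
    sub("claim_", "", ov$claim_type[i]),
    100 * ov$p[i], 100 * ov$lo[i], 100 * ov$hi[i]
  ))
}
cat("\nHigh in critical nutrients, with vs without claim:\n")
for (i in seq_len(nrow(fig2))) {
  cat(sprintf(
    "  %-18s with %5.1f%% (%.1f, %.1f)  without %5.1f%% (%.1f, %.1f)  CI non-overlap: %s\n",
    sub("claim_", "", fig2$claim_type[i]),
    100 * fig2$p_yes[i], 100 * fig2$lo_yes[i], 100 * fig2$hi_yes[i],
    100 * fig2$p_no[i], 100 * fig2$lo_no[i], 100 * fig2$hi_no[i],
    fig2$ci_nonoverlap[i]
  ))
}
cat("\nWrote the four prevalence tables under results/\n")
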