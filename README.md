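# foplabel

Tools for studying the tension between front-of-package (FoP) marketing
claims and the nutritional quality of packaged foods. The package
implements, as a tested and reusable pipeline, the two classification
systems such studies rest on, plus the prevalence analysis that joins
them, and a calibrated synthetic-data generator so the whole analysis can
be run end to end with known ground truth:

- **Nutrient profiling** — the PAHO nutrient profile model applied to
  nutrient-to-energy ratios: a product is *high in* a critical nutrient
  when free sugars contribute ≥ 10% of energy, total fats ≥ 30%,
  saturated fats ≥ 10%, trans fats ≥ 1%, or sodium reaches 1 mg/kcal
  (thresholds are configuration, not constants). A modification in the
  spirit of the Chilean labelling law (Law 20.606/2015) gates warning
  signs on evidence of *addition*: only products whose ingredient list
  shows added sugar, salt, or fat are eligible, and culinary ingredients
  (sugar, salt, oils, butter, milk creams) are never warned for the
  nutrients of their own identity — butter with added salt and sodium in
  excess gets a sodium warning, never a fat warning.
- **Ingredient screening** — keyword search in Portuguese ingredient
  lists for added sugar, salt, fat and nonnutritive sweeteners, with a
  token-boundary matching contract (the keyword *sal* never fires on
  *salsa*) and an editable, versioned lexicon.
- **Free-sugar estimation** — free sugars are not declared on Brazilian
  panels; they are estimated as a category-dependent fraction (0, 50%,
  75%, or 100%) of declared total sugars, only where total sugars are
  declared (never imputed).
- **Claim classification** — FoP text segments are classified into an
  INFORMAS-based taxonomy (health, nutrition, environment claims, with
  subcategories; nutrients *of concern* are saturated fat, trans fat,
  sugar, sodium) under the hierarchy health > nutrition > other.
- **Prevalence analysis** — claim prevalence by food category, and the
  proportion of products high in critical nutrients among products with
  vs without each claim type, with Wilson 95% confidence intervals
  compared by overlap.
- **Reliability metrics** — Cohen's kappa for double-entered claim codes
  and the two-way random-effects, absolute-agreement, single-measure ICC
  for double-entered nutrient values.
- **Synthetic label generator** — products over 25 reporting categories
  with full ground truth, calibrated so that in expectation 41.2% of
  products carry a claim (28.5% nutrition, 22.1% health, 5.2%
  environment), 10% declare total sugars, and 65.3% of nutrition-claim
  products vs 54.1% of the rest are high in a critical nutrient.

## Worked example

The butter rule, end to end from a raw record:

```r
library(foplabel)
butter <- product_record("butter", "Oils and Fats",
  energy_kcal = 720, total_fat_g = 80, saturated_fat_g = 52, sodium_mg = 900,
  ingredients_text = "creme de leite, sal", is_culinary = TRUE
)
prof <- profile_products(butter)
prof[, c("added_salt", "added_fat", "excess_total_fat", "excess_sodium",
         "eligible", "high_in_any")]
#> # A tibble: 1 × 6
#>   added_salt added_fat excess_total_fat excess_sodium eligible high_in_any
#>   <lgl>      <lgl>     <lgl>            <lgl>         <lgl>    <lgl>
#> 1 TRUE       TRUE      TRUE             TRUE          TRUE     TRUE
prof$warnings
#> [[1]]
#> [1] "sodium"
```

Fats are in excess (100% of energy) but intrinsic to a culinary
ingredient's identity, so the only warning sign is for sodium, the
nutrient added beyond it.

The full analysis over a simulated supply is the `analysis/` workflow:

```sh
Rscript analysis/01_simulate_supply.R 2017
Rscript analysis/02_nutrient_profiles.R
Rscript analysis/03_classify_claims.R
Rscript analysis/04_prevalence_tables.R
Rscript analysis/05_reliability.R 2017
```

which prints, among other things (seed 2017):

```
Claims found on 41.7% of products: nutrition 27.9%, health 22.0%, environment 5.7%.
Recovery of planted claim labels: 100.0% of products exact.

High in critical nutrients, with vs without claim:
  health             with  59.3% (55.8, 62.7)  without  56.4% (54.5, 58.2)  CI non-overlap: FALSE
  nutrition          with  62.5% (59.4, 65.5)  without  54.9% (52.9, 56.8)  CI non-overlap: TRUE
```

The sample proportions scatter around the calibrated expectations
(41.2%, 28.5%, 22.1%, 5.2%); the planted excess of high-in products
among nutrition-claim carriers is detected by CI non-overlap. All tables
land under `results/` as CSV. `run_full_analysis()` performs the same
steps in one call and writes a JSON run manifest; with a fixed seed its
outputs are byte-identical across runs.

## Layout

- `R/` — the implementation; `inst/extdata/` — editable YAML
  configuration (keyword lexicon, claim patterns, fraction map,
  thresholds), each versioned as a reconstruction.
- `analysis/` — the numbered workflow drivers shown above.
- `tests/testthat/` — unit, property and end-to-end suites backed by
  independently coded oracles.
- `vignettes/fop-labeling-methods.Rmd` — the methods vignette: model,
  assumptions, parameter choices, generator design, limitations.
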