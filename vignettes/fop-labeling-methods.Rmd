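---
title: "Methods: nutrient profiling, claim classification, and the synthetic label supply"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nutrient profiling, claim classification, and the synthetic label supply}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foplabel)
```

This vignette documents the models, rules and numerical choices behind
`foplabel`, and what the synthetic-data pipeline does and does not
demonstrate about real packaged-food data.

## The profiling model

A product is evaluated on nutrient-to-energy ratios, never absolute
amounts. Writing $E$ for energy (kcal) and using 4 kcal/g for sugars and
9 kcal/g for fats, the five excess flags are

$$\frac{4\,s_{\text{free}}}{E} \ge 0.10,\quad
  \frac{9\,f_{\text{tot}}}{E} \ge 0.30,\quad
  \frac{9\,f_{\text{sat}}}{E} \ge 0.10,\quad
  \frac{9\,f_{\text{trans}}}{E} \ge 0.01,\quad
  \frac{\text{Na (mg)}}{E} \ge 1,$$

with all thresholds and conversion factors read from an editable YAML
file carrying a provenance note (they restate the cited profile model's
recommendations; the thresholds are configuration so alternative rule
sets can be swapped in). Two consequences follow by construction and are
asserted as properties in the test suite: the flags are invariant to the
declared basis (per 100 g vs per portion — both sides of each ratio
scale together), and each flag is monotone in its own nutrient at fixed
energy.

Numerical conventions worth stating explicitly:

- **Boundary**: a ratio exactly at a threshold counts as excess (≥). The
  convention is documented rather than consequential — the generator
  draws continuous ratios, so exact boundaries have probability zero.
- **Not-evaluable is not "not in excess"**: products that do not declare
  total sugars get an `NA` free-sugar flag that never counts toward
  `high_in_any`; products with missing or non-positive energy are kept
  in the table, flagged not evaluable, and excluded from profiling
  rather than silently dropped.

## Eligibility and the culinary rule

Warning signs are gated on evidence of addition: a product is *eligible*
only if its ingredient list shows added sugar, added salt, or added fat
(the keyword screen below; the saturated-fat leg of the Chilean
criterion is operationalized through the fat keyword set, which is how
an ingredient list can express it). Culinary ingredients — sugar, salt,
oils, butter, milk creams — are additionally never warned for the
nutrients intrinsic to their identity (fats for the oils-and-fats
category, free sugars for table sugar), only for a critical nutrient
added beyond it. The canonical case: butter made of milk cream and salt,
in excess for fats and sodium, receives exactly the sodium warning.

A deliberate separation: `high_in_any` records whether any excess flag
is true — the product's nutritional profile, which is what the
prevalence analysis compares across claim groups — while `warnings` is
the eligibility- and culinary-filtered set of signs the product would
actually carry. Nonnutritive-sweetener presence is tracked alongside the
five nutrients and excluded from `high_in_any` by default
(`nns_in_high_in_any` in the threshold file flips this), since the five
critical nutrients, not NNS, define the "high in" outcome.

One wording tension is resolved in favour of the worked example: read
literally, "intrinsic nutrients are excluded *unless* another critical
nutrient was added in excess" would re-admit butter's fat warning
whenever its sodium is in excess, contradicting the butter case itself;
the implementation therefore never warns a culinary product for its
identity nutrients.

## Ingredient screening

The screen lowercases and accent-folds both text and keywords (explicit
character map, not locale transliteration, so results are
platform-independent), tokenizes on non-letter/digit boundaries, and
matches single-word keywords against whole tokens and multi-word
keywords against contiguous token runs. Naive substring search is wrong
in Portuguese — *sal* would fire on *salsa* (parsley) and *mel* on
*melão* (melon); the token contract plus an explicit trap set in the
generator keeps this honest. The shipped lexicon is a Portuguese
reconstruction of published English keyword glosses, versioned as such
and user-editable; plurals are listed explicitly instead of stemmed so
every match is auditable. Matching is deterministic and monotone in the
lexicon (adding keywords can only switch flags on), both asserted as
properties against a brute-force token-scan oracle.

## Free-sugar estimation

Brazilian panels declare total, not free, sugars, and declaration is
voluntary (the generator's default declaration rate is 10%). Free sugars
are estimated as $f \times \text{total sugars}$ with $f \in \{0, 0.50,
0.75, 1.00\}$ resolved from the product category and the added-sugar
flag. The published method fixes the boundary cases — beverages with no
intrinsic sugars count everything (soda: $f = 1$ regardless of the
keyword, since such sugars are free by nature), milk/yogurt with a sugar
keyword counts half — and the full category table is not published, so
the shipped map is a documented reconstruction: fruit-based products
with added sugar use 0.75 (they mix added and intrinsic sugars),
packaged produce and plain meats 0, and remaining categories with
negligible intrinsic sugars use 1 when the keyword is present. The map
is an editable YAML file; estimates are always within
$[0, \text{total sugars}]$ and never imputed for non-declaring products.

## Claim classification

Front-of-package segments are classified into the three-major taxonomy
(health, nutrition, environment) with subcategories, via a pattern
lexicon keyed by taxonomy cell. The original coding was manual; the
lexicon operationalizes it so the pipeline is runnable and testable end
to end — free-text generalization beyond the lexicon is explicitly out
of scope, and the generator's optional noisy-text mode exists precisely
to measure how recovery degrades when label text leaves the lexicon.
Resolution rules:

- Across majors, the documented hierarchy: health > nutrition >
  environment/other.
- Within health (the source is silent; chosen once and configurable):
  special diets > natural > general > others, on the grounds that the
  more specific claim should win ties.
- Within nutrition: of concern > not of concern > others, same
  rationale.

Pattern sets are pairwise non-nested across cells (a test sweeps the
lexicon through the classifier and requires every pattern to land in its
own cell), which is what makes generator recovery exact rather than
approximate. Only `fop_texts` is ever scanned: ingredient lists and
mandatory panel text are not claims.

## Prevalence analysis

Proportions carry Wilson score intervals by default — chosen for
boundary behaviour ($k = 0$ and $k = n$ still give informative
intervals); the method name is recorded in every output row and
Clopper-Pearson can be swapped in. Group contrasts are presented exactly
as the analysis plan frames them: two proportions with their intervals
and a non-overlap indicator, no hypothesis tests and no multiplicity
correction. Empirical coverage of the Wilson interval at nominal 95% is
checked by simulation (10,000 draws per grid point) and required to land
in 93–97%. A stratified 30% per-category sampler is provided for
workflow fidelity with the original subsampling design.

## The synthetic label supply

The generator emulates the statistical structure the analysis assumes,
with full ground truth emitted separately from the product table (the
analysis path consumes only the products):

- **Claim structure.** An any-claim Bernoulli (default marginal 0.412)
  is drawn first, with per-category prevalences varying around the
  marginal by a fixed relative pattern normalized so the mixture is
  exact; majors are then assigned to claim carriers by independent
  Bernoullis conditioned on at least one major, with probabilities
  solved (scalar fixed point, `solve_claim_allocation()`) so the implied
  marginals equal the nutrition/health/environment targets exactly.
  Independent unconditional majors could not reproduce the calibrated
  marginals — 0.285 + 0.221 + 0.052 > 0.412 forces positive
  co-occurrence of claim types. A consequence worth knowing: only the
  nutrition-claim association with high-in status is planted
  (0.653 vs 0.541); the health and environment contrasts the analysis
  reports on synthetic data emerge from this co-occurrence (both mildly
  positive) and are *not* calibrated to any published contrast.
- **Panels.** Per-category lognormal distributions on the ratio scale
  (nutrient shares of energy, sodium density), qualitatively ordered —
  cookies and processed meats usually in excess, packaged produce
  essentially never — but illustrative, not fitted to any dataset.
  Energy and basis are drawn separately; amounts are reconstructed from
  shares, so the engine's basis invariance is exercised by construction.
- **Association planting.** Each product receives a target high-in
  status from its nutrition-claim assignment; panels are redrawn from
  the category distribution for mismatching products (up to 20 rounds),
  and a deterministic construction forces the residue (sodium set above
  threshold with added salt to force high; all ratios drawn uniformly
  into (0.1, 0.85) of their thresholds to force not-high). The planted
  conditional proportions therefore hold exactly in expectation; the
  price is that forced products — concentrated in categories whose
  natural draws rarely match the target — are less category-typical.
- **Texts.** Ingredient lists are distractor tokens (including the trap
  words) plus one keyword per planted addition flag; claim segments are
  lexicon patterns verbatim. Segment-level recovery is consequently
  exact by construction: what the recovery tests demonstrate is pipeline
  correctness (plumbing, normalization, hierarchy), not natural-language
  robustness. Real labels paraphrase, abbreviate and misspell; the 100%
  recovery figure does not transfer to them, and the noisy-text mode
  (default off) quantifies exactly that gap.

Default scales: the acceptance-style checks run 200 replicates at
n = 3491 (the study-scale sample) for marginal recovery, 10,000 random
panels for engine/oracle equivalence, and n = 5000 for the end-to-end
determinism run; all sizes are chosen to make Monte-Carlo error small
relative to the 3-standard-error recovery bands while keeping a full
test run in minutes on one CPU.

## Reliability metrics

Cohen's kappa (unweighted; claim codes are nominal) with the degenerate
case `p_e = 1` returned as undefined-with-diagnostic rather than a
division by zero. The ICC variant is fixed to two-way random effects,
absolute agreement, single measure — the variant is recorded in the
output because "intraclass coefficient" underdetermines it; on simulated
double entries the estimate converges to
$\sigma^2_{\text{item}} / (\sigma^2_{\text{item}} + \sigma^2_{\text{noise}})$,
which the tests verify at planted variance ratios. Agreement bands use
the conventional 0.80 cut-off for "strong to almost perfect".

## Known limitations

- Lexicons (keywords, claim patterns, fraction map) are documented
  reconstructions, versioned as such; real-data use should expect to
  edit them.
- The generator plants a single conditional association and flat
  (category-independent) conditional probabilities; real data have
  category-specific associations.
- No market-share weighting, no survey design effects, no regression
  modelling — the analysis is deliberately restricted to prevalences
  with interval comparison.
- Sub-categories are sampled one per claim segment; real packages can
  carry several claims of the same major, which the per-product OR
  absorbs but the segment-level truth does not enumerate.
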