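# Excess thresholds for the nutrient profile engine.
# Provenance: the PAHO nutrient profile model's recommendations on
# nutrient-to-energy ratios (the source study cites the model without
# reprinting numbers); shipped as configuration so alternative rule sets
# can be swapped in. Boundary convention: a ratio exactly at a threshold
# counts as excess (>=).
provenance: "PAHO NPM energy-ratio thresholds (reconstruction; cited model, numbers not reprinted in the source study)"
energy_share:
  free_sugar: 0.10   # share of energy from free sugars
  total_fat: 0.30
  sat_fat: 0.10
  trans_fat: 0.01
sodium_mg_per_kcal: 1.0
kcal_per_g:
  sugar: 4.0
  fat: 9.0
track_nns: true
# Whether nonnutritive-sweetener presence counts toward high_in_any.
# Default false: NNS is tracked alongside, not among, the five critical
# nutrients.
nns_in_high_in_any: false
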