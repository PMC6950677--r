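# Free-sugar estimation map: category -> estimation class -> fraction of
# declared total sugars counted as free sugars. Reconstruction: the source
# NPM publishes the method (four levels: 0, 50%, 75%, 100%, by food group)
# and the boundary cases (soda-like beverages -> 100%; milk/yogurt with a
# sugar keyword -> 50%); the full category table is not published, so this
# default is a documented reconstruction. Edit freely.
version: "reconstruction-1.0"
fractions:
  none: 0.0
  half: 0.50
  three_quarters: 0.75
  full: 1.00
classes:
  all_free:
    - "Soda"
    - "Fruit-Flavored Drinks"
    - "Sugar and Nonnutritive Sweeteners"
    - "Candies and Desserts"
  dairy:
    - "Unsweetened Dairy Products"
    - "Sweetened Dairy Products"
    - "Cheese"
  fruit_based:
    - "Juices"
    - "Nectars"
    - "Fruit Preserve"
  intrinsic_only:
    - "Packaged Fruits and Vegetables"
    - "Meat, Poultry, Seafood, and Egg"
  added_when_flagged:
    - "Breakfast Cereals and Granola Bars"
    - "Bakery Products"
    - "Convenience Foods"
    - "Salty Snacks"
    - "Cookies"
    - "Canned Vegetables"
    - "Oils and Fats"
    - "Sauces and Dressings"
    - "Coffee and Tea"
    - "Cereals, Beans, Other Grain Products"
    - "Processed Meats"
    - "Other Beverages"
    - "Nuts and Seeds"
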