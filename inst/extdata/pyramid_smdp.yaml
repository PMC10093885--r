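# Sustainable Mediterranean-diet pyramid (revision of the traditional pyramid
# admitting modern food categories such as chocolate, soft drinks and frozen
# desserts). Tiers base-to-top; see pyramid_tmdp.yaml for the field meanings.
# Every subcategory mapped by the traditional pyramid is also mapped here, so
# foods eligible under the traditional pyramid are a subset of those eligible
# under the sustainable one.
pyramid: sMDP
tiers:
  - Fruits, Vegetables, Cereals
  - Olives, Pulses, Nuts
  - Dairy
  - White meat, fish, eggs
  - Red and processed Meat
  - Sweets
frequency:
  Fruits, Vegetables, Cereals: daily
  Olives, Pulses, Nuts: daily
  Dairy: daily
  White meat, fish, eggs: weekly
  Red and processed Meat: monthly
  Sweets: monthly
mapping:
  Fine Bakery Ware: Sweets
  Sugar, Honey or Syrup: Sweets
  Jam or Marmalade: Sweets
  Non-chocolate confectionary or other sugar product: Sweets
  Prepared Food Product: Sweets
  Frozen dairy dessert: Sweets
  Cereal or cereal milling product: Sweets
  Chocolate: Sweets
  Juice or Nectar: Sweets
  Non-alcoholic beverages: Sweets
  Preserved Meat: Red and processed Meat
  Sausage or similar meat product: Red and processed Meat
  Meat dish: Red and processed Meat
  Fresh or Processed Egg: White meat, fish, eggs
  Seafood Product: White meat, fish, eggs
  Milk: Dairy
  Yogurt: Dairy
  Cheese: Dairy
  Pulses: Olives, Pulses, Nuts
  Nut or Seed Product: Olives, Pulses, Nuts
  Seeds or Kernel: Olives, Pulses, Nuts
  Nuts: Olives, Pulses, Nuts
  Vegetable: Fruits, Vegetables, Cereals
  Processed fruit: Fruits, Vegetables, Cereals
  Starchy Root or Potato: Fruits, Vegetables, Cereals
  Rice or Similar Product: Fruits, Vegetables, Cereals
  Pasta or Similar product: Fruits, Vegetables, Cereals
  Bread or similar product: Fruits, Vegetables, Cereals
alternatives:
  Vegetable:
    - Olives, Pulses, Nuts
  Prepared Food Product:
    - White meat, fish, eggs
    - Olives, Pulses, Nuts
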