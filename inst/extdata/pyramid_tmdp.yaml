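# Traditional Mediterranean-diet pyramid (1960s Crete pattern).
# Tiers are listed base-to-top; `frequency` tags the recommended consumption
# cadence of each tier. `mapping` assigns each eligible food subcategory its
# (primary) tier; `alternatives` lists further tiers a subcategory may occupy,
# selectable per food through an optional `tier_hint` column.
pyramid: tMDP
tiers:
  - Non refined cereals
  - Fruits and Vegetables
  - Olives, Pulses, Nuts
  - Dairy
  - Fish
  - Eggs
  - Potatoes
  - Sweets
  - Red Meat
frequency:
  Non refined cereals: daily
  Fruits and Vegetables: daily
  Olives, Pulses, Nuts: daily
  Dairy: daily
  Fish: weekly
  Eggs: weekly
  Potatoes: weekly
  Sweets: weekly
  Red Meat: monthly
mapping:
  Preserved Meat: Red Meat
  Sausage or similar meat product: Red Meat
  Meat dish: Red Meat
  Fine Bakery Ware: Sweets
  Sugar, Honey or Syrup: Sweets
  Jam or Marmalade: Sweets
  Non-chocolate confectionary or other sugar product: Sweets
  Prepared Food Product: Sweets
  Fresh or Processed Egg: Eggs
  Starchy Root or Potato: Potatoes
  Pulses: Olives, Pulses, Nuts
  Nut or Seed Product: Olives, Pulses, Nuts
  Seeds or Kernel: Olives, Pulses, Nuts
  Nuts: Olives, Pulses, Nuts
  Vegetable: Fruits and Vegetables
  Seafood Product: Fish
  Milk: Dairy
  Yogurt: Dairy
  Cheese: Dairy
  Processed fruit: Fruits and Vegetables
  Rice or Similar Product: Non refined cereals
  Pasta or Similar product: Non refined cereals
  Bread or similar product: Non refined cereals
alternatives:
  Vegetable:
    - Olives, Pulses, Nuts
  Prepared Food Product:
    - Olives, Pulses, Nuts
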