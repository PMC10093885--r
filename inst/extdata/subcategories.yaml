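# Controlled vocabulary for the `subcategory` field of a branded-food table.
#
# `mapped` lists subcategories that belong to a tier of at least one
# Mediterranean-diet pyramid (see pyramid_tmdp.yaml / pyramid_smdp.yaml);
# `unmapped` lists packaged-food subcategories with no pyramid tier, which the
# tier-assignment step reports as modern (ineligible) foods.
mapped:
  - Preserved Meat
  - Sausage or similar meat product
  - Meat dish
  - Fine Bakery Ware
  - Sugar, Honey or Syrup
  - Jam or Marmalade
  - Non-chocolate confectionary or other sugar product
  - Prepared Food Product
  - Frozen dairy dessert
  - Cereal or cereal milling product
  - Chocolate
  - Juice or Nectar
  - Non-alcoholic beverages
  - Fresh or Processed Egg
  - Seafood Product
  - Starchy Root or Potato
  - Pulses
  - Nut or Seed Product
  - Seeds or Kernel
  - Nuts
  - Vegetable
  - Processed fruit
  - Milk
  - Yogurt
  - Cheese
  - Rice or Similar Product
  - Pasta or Similar product
  - Bread or similar product
unmapped:
  - Extruded Snack
  - Instant Noodle Dish
  - Energy Drink
  - Water
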