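---
title: "Food-level analysis of branded foods: NOVA, FSAm-NPS and Mediterranean-diet pyramid mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Food-level analysis of branded foods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(novamed)
```

## The problem

Packaged ("branded") foods carry two label artefacts that can be analysed at
scale: a free-text ingredient list and a per-100 g/mL nutrition declaration.
From those two inputs, three food-level constructs are widely used in
nutrition research and policy:

* **NOVA** classifies foods by the extent and purpose of processing into
  four groups: unprocessed/minimally processed foods (NOVA1), processed
  culinary ingredients such as salt, sugar, oils and flours (NOVA2),
  traditionally processed foods that combine the two (NOVA3), and
  ultra-processed foods (UPFs, NOVA4) — industrial formulations recognisable
  by marker ingredients (additives, flavourings, protein isolates,
  industrial sweeteners and the like).
* **FSAm-NPS / Nutri-Score** summarises nutritional quality. Four
  "negative" components — energy (kJ), total sugars (g), saturated fat (g)
  and sodium (mg) — each score 0–10 points; three "positive" components —
  protein (g), fiber (g) and the fruit/vegetable/pulse/nut fraction (FV%) —
  each score 0–5. The score `S = N − P` lies in −15..+40 and maps to the
  five-letter Nutri-Score grade (A best to E worst) with basis-specific
  cut-offs; among beverages only waters can be graded A.
* **Mediterranean-diet pyramids** express food-based dietary guidelines as
  tiers with daily/weekly/monthly consumption recommendations. The
  traditional pyramid (tMDP) reflects the 1960s Cretan pattern; the
  sustainable revision (sMDP) admits modern food categories (chocolate,
  soft drinks, frozen desserts) in its upper tiers.

This package implements all three constructs as a reusable, tested pipeline
over a common branded-food table, together with the nonparametric
group-comparison tables used to report how NOVA groups distribute across
pyramid tiers and how their nutrient content and Nutri-Score differ.

## The data model

A food table is a tibble with one row per product: identity (`id`, `name`),
a `subcategory` from a controlled vocabulary, the scoring `basis` (solid or
beverage), three flags (`is_water`, `is_composite_dish`,
`is_plant_based_imitation`), the free-text `ingredient_text`, and the
nutrient panel per 100 g/mL (`energy_kcal`, `protein_g`, `total_fat_g`,
`sfa_g`, `sugars_g`, `salt_g`, `fiber_g`, `fv_percent`).

Missingness is first-class: `NA` is *not* zero. A missing negative nutrient
makes the FSAm-NPS score incomputable and excludes the food from scoring; a
missing positive nutrient is imputed to zero (and recorded). CSV encodes
missing values as empty cells, JSON as `null`, and the readers/writers
round-trip the distinction exactly. Validation (`validate_foods()`) reports
every violated invariant (negative amounts, saturated fat above total fat,
sugars or FV% above 100, waters not declared as beverages, duplicate ids)
without throwing.

Two unit conversions bridge the label scale to the scoring scale: energy
kcal→kJ with the thermochemical 4.184 kJ/kcal, and salt→sodium with the EU
labelling convention salt = sodium × 2.5, i.e. `sodium_mg = salt_g × 400`.
Neither factor is normative in the scoring literature's table headers, so
both are implemented as explicit, tested functions.

## NOVA classification

`classify_nova()` is purely ingredient-driven; subcategories never override
it (real markets show cheeses splitting between NOVA3 and NOVA4, so
hard-coding categories would beg the question the analysis asks).

Normalisation (`normalize_ingredient_text()`) lower-cases the text, strips
percentage annotations and bracketed quantities ("(5%)", "[30 g]"), and
splits on top-level commas and semicolons only, so parenthesised
sub-ingredients stay attached to their parent clause.

Matching is case-folded substring-at-word-boundary by default: the marker
"soy lecithin" matches inside the token "emulsifier: soy lecithin", but
"aroma" does not match "aromatic". An exact whole-token mode is available
through the lexicon's `matching_policy`.

The decision rule, in precedence order:

1. no readable ingredient text → `UNCLASSIFIABLE` (excluded from all
   denominators downstream);
2. ≥ 1 ultra-processing marker hit → NOVA4 — any industrial additive forces
   NOVA4 regardless of everything else;
3. a single token matching a culinary term, possibly accompanied by plain
   water (brine/syrup carriers) → NOVA2;
4. ≥ 1 culinary hit alongside ≥ 1 non-culinary token → NOVA3;
5. otherwise → NOVA1.

Two edge cases were genuinely open and are resolved as follows. A product
whose tokens are *all* culinary but more than one (e.g. "salt, sugar") falls
through to NOVA1 under rule 5; such products essentially do not occur in
label data and the alternative (extending NOVA2 to multi-substance blends)
would blur the "single isolated substance" meaning of that group. Second,
"water" is ignored only in the single-substance test, never counted as a
culinary ingredient, so "green beans, water, salt" is NOVA3 while "salt,
water" remains NOVA2.

The default lexicon (`default_lexicon()`, shipped as YAML, swappable for
other languages) seeds every marker class named in the NOVA literature:
sweeteners, industrial sodium salts, industrial oils/fats, protein
isolates/concentrates, flavourings and flavour enhancers, emulsifiers,
thickeners and bulking agents, antioxidants/preservatives, fortificants,
and other industrial auxiliaries. Culinary oils (olive, sunflower, corn,
sesame…) live in the culinary set; industrial fats (palm and hydrogenated
oils, margarine) are NOVA4 markers — the two sets are validated to be
disjoint. The lexicon makes no claim of E-number completeness; it is a
configuration file, not a fixed vocabulary.

```{r}
classify_nova(list(id = "choc",
  ingredient_text = "Sugar (5%), cocoa mass, emulsifier: soy lecithin"))[, 1:4]
```

## FSAm-NPS scoring and Nutri-Score grading

The component threshold tables (`default_score_tables()`, shipped as YAML)
are the published 2017 FSA/FSAm-NPS tables: energy in kJ steps of 335 up to
3350, sugars 4.5–45 g, saturated fat 1–10 g, sodium 90–900 mg for solids;
the finer beverage scales for energy and sugars; protein 1.6–8.0 g and
fiber 0.9–4.7 g for the positives; FV% bands at 40/60/80. Points are the
count of thresholds *strictly* below the declared value, so boundary values
take the lower band, and values are used as declared, unrounded.

Two scoring modes exist:

* `paper_subtraction` (default): `S = N − P` with every positive component
  capped at 5, preserving the nominal −15..+40 range on both bases (the
  official beverage FV scale reaches 10; the cap keeps the printed range).
* `full_rule`: the official restriction — protein is not counted when
  `N ≥ 11`, unless the FV component is at its maximum or the food is a
  cheese (`subcategory == "Cheese"`).

Grades: waters are always A; solids map −15..−1 → A, 0–2 → B, 3–10 → C,
11–18 → D, 19–40 → E; non-water beverages −15..1 → B, 2–5 → C, 6–9 → D,
10–40 → E. The nominal presentation of the solid A band as "−5 to −1" is
read as a display floor: every published grade map sends all scores ≤ −1 to
A, and leaving −15..−6 ungraded would make valid scores unmappable.

```{r}
egg <- list(id = "egg", basis = "solid", energy_kcal = 46, protein_g = 11,
            total_fat_g = 0.3, sfa_g = 0, sugars_g = 0.3, salt_g = 0.44)
fsam_nps(egg)[, c("n_points", "p_points", "score", "grade")]
```

The only point this product collects on the negative side is one sodium
point (0.44 g salt → 176 mg sodium > 90), while 11 g protein saturates the
protein component, giving `S = 1 − 5 = −4`, grade A.

## Pyramid eligibility and tier assignment

`assign_tier()` is keyed on subcategory plus flags only — nutrient content
and NOVA group never affect eligibility, because the distribution of NOVA
groups *within* tiers is the analysis outcome, not an input. Precedence:
plant-based meat/dairy imitations are excluded from both pyramids, then
composite traditional dishes (moussaka-style products that fit no single
tier), then subcategories absent from a pyramid's mapping are modern
(ineligible) foods; everything else receives its mapped tier.

The default mappings (shipped as YAML per pyramid) enumerate the
subcategory→tier pairs of the two pyramids; every subcategory mapped by the
traditional pyramid is also mapped by the sustainable one, which makes the
tMDP-eligible set provably a subset of the sMDP-eligible set. A few
subcategories legitimately occur under several tiers (e.g. "Vegetable"
products are mostly a fruits-and-vegetables item but olives belong with
pulses and nuts). The config assigns the majority tier as primary and lists
the others as alternatives, selectable per food through an optional
`tier_hint` column; the exact screening criteria used by the original
compilers are not public, so this reconstruction is a documented
approximation.

## Statistics and reporting tables

All summaries are nonparametric, matching skewed label data:

* `median_iqr()` uses the weighted-average `(n+1)p` quantile definition
  (R's type 6), the default of the commercial statistics environment these
  analyses are traditionally run in — medians differ between definitions at
  small n, so the choice is pinned and tested.
* `mann_whitney_u()` is exact by enumeration when the combined sample size
  is ≤ 12 with no ties, otherwise it uses the normal approximation with
  tie-corrected variance and continuity correction. The two branches agree
  to within 0.02 in p at the crossover size (a tested property).
* `kruskal_wallis()` reports the tie-corrected H with the chi-squared tail.
* Any comparison involving a group with fewer than two observations is
  reported `"n.a."`, never as a p-value.

The table builders mirror the standard reporting layout:
`nova_distribution_table()` (market-level NOVA shares per scope),
`tier_nova_crosstab()` (tier and tier×subcategory NOVA counts with row
percentages; empty cells omitted), `nutrient_comparison_table()`
(median (Q1, Q3) of energy, protein, total fat, SFA, sugars, salt per
tier×NOVA cell) and `nutriscore_distribution_table()` (mean ± SD of the
FSAm-NPS score — the conventional presentation for this table, with the
median/IQR also emitted — plus grade counts A–E).

Testing scheme per tier×variable family: a Kruskal–Wallis omnibus test when
at least three NOVA groups have n ≥ 2, a Mann–Whitney test when exactly
two; pairwise NOVA1-vs-NOVA4 and NOVA3-vs-NOVA4 Mann–Whitney tests are
Bonferroni-adjusted by the number of pairs actually tested within that
family (capped at 1). The significance level defaults to α = 0.01: the
source conventions state a "0.01%" level alongside "99% confidence", which
are contradictory, and the percent sign is treated as a typo — α is a
plain parameter for users who disagree.

## The synthetic database generator

`generate_food_db()` exists so that every pipeline stage is testable with
known ground truth and no data download. It emulates the *structure* of a
national branded-food database — subcategory blocks with their own nutrient
distributions, ingredient texts with or without UPF markers, plausible
missing-value patterns, composite/imitation flags — while making no claim
to reproduce any real market's percentages.

Design choices, fixed once:

* **Construction guarantees labels.** NOVA4 texts embed ≥ 1 marker term
  from the default lexicon, NOVA3 texts a culinary term plus a base food
  token, NOVA2 a single culinary term, NOVA1 only base tokens. Distractor
  tokens are drawn from a pool verified disjoint from the lexicon and are
  never added to NOVA2 foods (a second token would correctly turn them into
  NOVA3). Label recovery is therefore exact by construction, and the tests
  assert it at 100%.
* **Per-block RNG streams.** Each block's stream is seeded from the
  top-level seed and the subcategory name, so adding or removing a block
  never perturbs the others — stable fixtures under config evolution.
* **Nutrients are log-normal** (non-negative, right-skewed like label
  data), parameterised by median and log-scale dispersion; dispersion 0
  gives fixed values for exact tests. Saturated fat is generated as a
  fraction of total fat so the panel invariant holds by construction.
* **Missingness**: each of the four negative nutrients is masked
  independently with probability 0.05 per food, giving an overall scoring
  exclusion of 1 − 0.95⁴ ≈ 18.5%, the magnitude seen in real branded
  databases; positive nutrients are masked at 5% (under the <10% reported
  for real data). These rates are study conditions, not tuning knobs.
* **Default size**: 31 blocks covering every subcategory of both pyramid
  vocabularies plus three modern ones, 2106 foods in total — large enough
  for distributional tests to be meaningful, small enough that the whole
  suite (including two full classify-score-assign passes) runs in about a
  minute on one core.

What passing tests on synthetic data do **not** show: robustness to
real-world label noise (spelling variants, Greek-language ingredient
lists, E-number-only declarations, marker terms the lexicon lacks), nor
correctness of any particular market share. Those require a real database
and, for other languages, a swapped-in lexicon.

## Numerical and degenerate-input conventions

* Threshold comparisons are strict (`value > threshold`); boundary values
  take the lower point band.
* Scores are exact integers (sums of integer points); no floating-point
  comparison tolerances are needed anywhere in scoring.
* Empty tables propagate as empty, typed results through every operation.
* Percentages in distribution rows always sum to 100 within 0.1 by
  construction; empty tier×NOVA cells are omitted from tables rather than
  printed as zeros.
* `UNCLASSIFIABLE` foods (no ingredient text) and scoring-excluded foods
  are dropped from the relevant denominators and counted in the exclusion
  log of `run_food_analysis()`.

## Known limitations

* The NOVA1/2/3 side of the decision tree is a documented reconstruction;
  published analyses rarely state their full rule below the NOVA4 marker
  search, and different reconstructions can shift the small NOVA2/NOVA3
  groups.
* The lexicon is English and finite; NOVA4 sensitivity on real labels is
  bounded by lexicon coverage.
* The 2023 revision of the Nutri-Score algorithm is out of scope, as are
  per-portion scoring and added-sugar distinctions.
* Pyramid screening reconstructs a subcategory-level rule from published
  tier enumerations; per-food adjudication by the original compilers is
  not reproducible.
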