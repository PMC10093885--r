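# Shared fixtures: quick food constructors and an independent brute-force
# NOVA oracle used to cross-check the classifier.

make_food <- function(id = "f1", name = "food", subcategory = "Pulses",
                      basis = "solid", is_water = FALSE,
                      is_composite_dish = FALSE,
                      is_plant_based_imitation = FALSE,
                      ingredient_text = "chickpeas",
                      energy_kcal = 100, protein_g = 5, total_fat_g = 2,
                      sfa_g = 0.5, sugars_g = 1, salt_g = 0.1,
                      fiber_g = NA_real_, fv_percent = NA_real_) {
  tibble::tibble(
    id = id, name = name, subcategory = subcategory, basis = basis,
    is_water = is_water, is_composite_dish = is_composite_dish,
    is_plant_based_imitation = is_plant_based_imitation,
    ingredient_text = ingredient_text,
    energy_kcal = energy_kcal, protein_g = protein_g,
    total_fat_g = total_fat_g, sfa_g = sfa_g, sugars_g = sugars_g,
    salt_g = salt_g, fiber_g = fiber_g, fv_percent = fv_percent
  )
}

make_food_table <- function(...) {
  dplyr::bind_rows(...)
}

# --- brute-force NOVA oracle -------------------------------------------------
# Re-derives the decision tree by plain scanning: a term matches a token when
# the term's word sequence occurs as consecutive words of the token (words =
# maximal alphanumeric runs). No regexes, no indexing, no short-circuiting.

oracle_words <- function(s) {
  w <- strsplit(tolower(s), "[^[:alnum:]]+")[[1]]
  w[nzchar(w)]
}

oracle_contains <- function(token, term) {
  tw <- oracle_words(token)
  mw <- oracle_words(term)
  if (length(mw) == 0 || length(tw) < length(mw)) return(FALSE)
  found <- FALSE
  for (i in seq_len(length(tw) - length(mw) + 1)) {
    ok <- TRUE
    for (j in seq_along(mw)) if (tw[i + j - 1] != mw[j]) ok <- FALSE
    if (ok) found <- TRUE
  }
  found
}

oracle_nova <- function(tokens, lexicon) {
  if (length(tokens) == 0) return("UNCLASSIFIABLE")
  any_marker <- FALSE
  for (tok in tokens) {
    for (term in lexicon$upf_markers$term) {
      if (oracle_contains(tok, term)) any_marker <- TRUE
    }
  }
  if (any_marker) return("NOVA4")
  culinary <- vapply(tokens, function(tok) {
    hit <- FALSE
    for (term in lexicon$culinary_terms) {
      if (oracle_contains(tok, term)) hit <- TRUE
    }
    hit
  }, logical(1))
  non_water <- tokens != "water"
  if (sum(non_water) == 1 && culinary[non_water]) return("NOVA2")
  if (any(culinary) && any(!culinary)) return("NOVA3")
  "NOVA1"
}

# random token lists mixing marker terms, culinary terms, neutral food words
# and water, for classifier/oracle agreement checks
random_token_lists <- function(n, lexicon, seed = 1) {
  set.seed(seed)
  neutral <- c("chickpeas", "cocoa mass", "milk", "tomatoes", "oats",
               "almonds", "sardines", "rye", "peaches", "spinach",
               "dried figs", "carob extract", "rice")
  pool <- c(sample(lexicon$upf_markers$term, 30), lexicon$culinary_terms,
            neutral, "water")
  lapply(seq_len(n), function(i) {
    k <- sample(1:5, 1)
    tokens <- sample(pool, k, replace = TRUE)
    # occasionally embed a term inside a longer clause
    wrap <- runif(k) < 0.3
    tokens[wrap] <- paste("organic", tokens[wrap])
    tokens
  })
}
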