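# Synthetic branded-food database generator.
#
# Each subcategory block draws its products from its own seeded RNG stream
# (derived from the top-level seed and the subcategory name), so adding or
# reordering blocks never perturbs the output of the others. Ingredient
# texts are assembled so that the default lexicon provably recovers the
# intended NOVA group: NOVA4 foods carry at least one ultra-processing
# marker term, NOVA3 foods a culinary term plus a base food token, NOVA2
# foods a single culinary term, NOVA1 foods only base tokens; optional
# distractor tokens are disjoint from the lexicon and are never added to
# NOVA2 foods (which would change the single-substance rule).

#' Default synthetic-database configuration
#'
#' One block per subcategory of the default pyramid vocabulary (plus three
#' modern, pyramid-ineligible subcategories), with NOVA mixes qualitatively
#' echoing the branded-food market (pulses all NOVA1, fine bakery ware all
#' NOVA4, cheese split NOVA3/NOVA4, ...), log-normal nutrient generators,
#' a 5% per-nutrient missing rate for the four negative nutrients (overall
#' scoring exclusion of about 18.5%) and a 5% missing rate for the positive
#' nutrients.
#'
#' @return A `synth_config` list (see [generate_food_db()]).
#' @export
default_synth_config <- function() {
  lex <- default_lexicon()
  blk <- function(subcategory, n, mix, energy, protein, fat, sugars, salt,
                  sfa_frac = c(0.2, 0.5), basis = "solid", fiber = NULL,
                  fv = NULL, nova2_terms = NULL, base_tokens,
                  p_composite = 0, p_imitation = 0) {
    list(subcategory = subcategory, n = n, basis = basis, nova_mix = mix,
         nutrients = list(energy_kcal = energy, protein_g = protein,
                          total_fat_g = fat, sugars_g = sugars, salt_g = salt),
         sfa_frac = sfa_frac, fiber = fiber, fv = fv,
         nova2_terms = nova2_terms, base_tokens = base_tokens,
         p_composite = p_composite, p_imitation = p_imitation,
         p_missing_neg = 0.05, p_missing_pos = 0.05)
  }
  ln <- function(median, dispersion = 0.3) list(median = median,
                                                dispersion = dispersion)
  fx <- function(value) list(fixed = value)
  m <- function(...) {
    x <- c(...)
    x / sum(x)
  }
  blocks <- list(
    blk("Preserved Meat", 30, m(NOVA4 = 1), ln(210), ln(14), ln(15), ln(1), ln(2.4, 0.15),
        base_tokens = c("pork", "beef")),
    blk("Sausage or similar meat product", 25, m(NOVA4 = 1), ln(250), ln(13), ln(20), ln(1), ln(2.2, 0.15),
        base_tokens = c("pork", "chicken meat")),
    blk("Meat dish", 6, m(NOVA4 = 1), ln(180), ln(12), ln(9), ln(1.5), ln(1.2),
        base_tokens = c("beef", "tomatoes"), p_composite = 0.5),
    blk("Fine Bakery Ware", 150, m(NOVA4 = 1), ln(450), ln(6), ln(20), ln(30), ln(0.4),
        sfa_frac = c(0.4, 0.6), base_tokens = c("wheat flour", "eggs", "cocoa mass")),
    blk("Sugar, Honey or Syrup", 40, m(NOVA2 = 0.95, NOVA3 = 0.05), ln(310, 0.1), ln(0.4, 0.5),
        ln(0.05, 0.5), ln(75, 0.1), ln(0.02, 0.5),
        nova2_terms = c("honey", "sugar"), base_tokens = c("carob extract")),
    blk("Jam or Marmalade", 50, m(NOVA4 = 1), ln(240), ln(0.5), ln(0.1, 0.5), ln(55), ln(0.03),
        fv = ln(45, 0.15), base_tokens = c("strawberries", "apricots")),
    blk("Non-chocolate confectionary or other sugar product", 50,
        m(NOVA3 = 0.3, NOVA4 = 0.7), ln(380), ln(1.5), ln(1, 0.6), ln(70), ln(0.05),
        base_tokens = c("sesame seeds", "dried figs")),
    blk("Prepared Food Product", 45, m(NOVA4 = 1), ln(200), ln(6), ln(9), ln(4), ln(1),
        base_tokens = c("vine leaves", "tomatoes", "eggplant"), p_composite = 0.3),
    blk("Frozen dairy dessert", 30, m(NOVA4 = 1), ln(220), ln(3.5), ln(11), ln(22), ln(0.15),
        sfa_frac = c(0.5, 0.7), base_tokens = c("milk", "cream")),
    blk("Cereal or cereal milling product", 8, m(NOVA4 = 1), ln(380), ln(8), ln(4), ln(22), ln(0.5),
        base_tokens = c("oats", "wheat"), fiber = ln(5)),
    blk("Chocolate", 110, m(NOVA4 = 1), ln(540), ln(6.5), ln(32), ln(48), ln(0.2),
        sfa_frac = c(0.55, 0.65), base_tokens = c("cocoa mass", "cocoa butter")),
    blk("Juice or Nectar", 90, m(NOVA1 = 0.3, NOVA4 = 0.7), ln(45, 0.2), ln(0.5, 0.4),
        ln(0.05, 0.5), ln(10, 0.2), ln(0.01, 0.5), basis = "beverage",
        fv = fx(100), base_tokens = c("orange juice", "apple juice", "peach pulp")),
    blk("Non-alcoholic beverages", 110, m(NOVA4 = 1), ln(40, 0.4), ln(0.05, 0.5),
        ln(0.02, 0.5), ln(9, 0.4), ln(0.02, 0.5), basis = "beverage",
        base_tokens = c("carbonated water")),
    blk("Fresh or Processed Egg", 30, m(NOVA1 = 0.97, NOVA4 = 0.03), ln(140, 0.05),
        ln(13, 0.05), ln(10, 0.1), ln(0.3, 0.4), ln(0.3, 0.2), sfa_frac = c(0.28, 0.32),
        base_tokens = c("eggs")),
    blk("Seafood Product", 50, m(NOVA3 = 0.7, NOVA4 = 0.3), ln(180), ln(19), ln(9, 0.6),
        ln(0.5, 0.6), ln(1.1, 0.3), base_tokens = c("sardines", "tuna", "anchovies")),
    blk("Starchy Root or Potato", 12, m(NOVA1 = 0.1, NOVA3 = 0.1, NOVA4 = 0.8),
        ln(130), ln(2.3, 0.15), ln(4, 0.6), ln(1, 0.5), ln(0.25, 0.5),
        base_tokens = c("potatoes"), fiber = ln(2)),
    blk("Pulses", 250, m(NOVA1 = 1), ln(331, 0.1), ln(22, 0.1), ln(1.7, 0.3),
        ln(2.4, 0.3), ln(0.02, 0.5), fiber = ln(6, 0.2), fv = fx(100),
        base_tokens = c("chickpeas", "lentils", "split peas", "red kidney beans")),
    blk("Nut or Seed Product", 15, m(NOVA1 = 0.4, NOVA4 = 0.6), ln(560), ln(20), ln(48),
        ln(4), ln(0.3, 0.6), fv = fx(100), base_tokens = c("peanuts", "tahini")),
    blk("Seeds or Kernel", 30, m(NOVA3 = 0.5, NOVA4 = 0.5), ln(550), ln(19), ln(46),
        ln(3), ln(1.5), fv = fx(100), base_tokens = c("pumpkin seeds", "sesame seeds")),
    blk("Nuts", 40, m(NOVA1 = 0.3, NOVA3 = 0.15, NOVA4 = 0.55), ln(600), ln(18), ln(52),
        ln(4), ln(0.8, 0.8), fv = fx(100), fiber = ln(7, 0.2),
        base_tokens = c("almonds", "walnuts", "hazelnuts", "pistachios")),
    blk("Vegetable", 160, m(NOVA1 = 0.37, NOVA3 = 0.17, NOVA4 = 0.46), ln(45, 0.5),
        ln(2.5, 0.4), ln(0.4, 0.5), ln(3.5, 0.5), ln(0.2, 0.9), fv = fx(95),
        fiber = ln(2.5), base_tokens = c("tomatoes", "green beans", "spinach",
                                         "artichokes", "peas")),
    blk("Processed fruit", 25, m(NOVA1 = 0.05, NOVA3 = 0.1, NOVA4 = 0.85), ln(80),
        ln(0.6, 0.4), ln(0.2, 0.5), ln(16), ln(0.02, 0.5), fv = fx(90),
        base_tokens = c("peaches", "apricots", "figs")),
    blk("Milk", 110, m(NOVA1 = 0.5, NOVA3 = 0.05, NOVA4 = 0.45), ln(55, 0.25),
        ln(3.4, 0.1), ln(2.2, 0.5), ln(4.8, 0.2), ln(0.11, 0.15), sfa_frac = c(0.6, 0.7),
        base_tokens = c("milk"), p_imitation = 0.1),
    blk("Yogurt", 80, m(NOVA1 = 0.3, NOVA4 = 0.7), ln(85, 0.3), ln(4.5, 0.3), ln(3.5, 0.6),
        ln(5, 0.4), ln(0.12, 0.2), sfa_frac = c(0.6, 0.7),
        base_tokens = c("milk", "yogurt cultures"), p_imitation = 0.05),
    blk("Cheese", 120, m(NOVA3 = 0.6, NOVA4 = 0.4), ln(300, 0.25), ln(22, 0.2), ln(23, 0.25),
        ln(0.6, 0.6), ln(1.75, 0.2), sfa_frac = c(0.6, 0.7),
        base_tokens = c("milk", "rennet"), p_imitation = 0.05),
    blk("Rice or Similar Product", 50, m(NOVA1 = 0.85, NOVA4 = 0.15), ln(350, 0.05),
        ln(7.5, 0.1), ln(1, 0.4), ln(0.5, 0.5), ln(0.01, 0.5), fiber = ln(1.5),
        base_tokens = c("rice", "brown rice")),
    blk("Pasta or Similar product", 100, m(NOVA1 = 0.9, NOVA4 = 0.1), ln(355, 0.05),
        ln(12, 0.1), ln(1.6, 0.2), ln(3.3, 0.3), ln(0.02, 0.6), fiber = ln(3),
        base_tokens = c("durum wheat semolina")),
    blk("Bread or similar product", 90, m(NOVA4 = 1), ln(400, 0.15), ln(11, 0.1),
        ln(7.5, 0.5), ln(4.5, 0.3), ln(1.1, 0.2), fiber = ln(4),
        base_tokens = c("wheat flour", "rye")),
    # modern, pyramid-ineligible subcategories
    blk("Extruded Snack", 100, m(NOVA4 = 1), ln(500), ln(6), ln(28), ln(3), ln(1.6),
        base_tokens = c("corn", "potatoes")),
    blk("Instant Noodle Dish", 40, m(NOVA4 = 1), ln(440), ln(9), ln(18), ln(4), ln(3.5),
        base_tokens = c("wheat flour")),
    blk("Energy Drink", 60, m(NOVA4 = 1), ln(45, 0.3), ln(0.1, 0.5), ln(0.02, 0.5),
        ln(11, 0.3), ln(0.1, 0.5), basis = "beverage",
        base_tokens = c("carbonated water"))
  )
  structure(list(
    seed = 20230403,
    distractor_rate = 0.5,
    distractor_pool = c("oregano", "basil", "thyme", "rosemary", "paprika",
                        "black pepper", "garlic", "onion", "lemon zest",
                        "cinnamon", "turmeric", "cumin"),
    culinary_pool = c("salt", "sugar", "olive oil"),
    upf_marker_pool = c("emulsifier: soy lecithin", "xanthan gum",
                        "glucose syrup", "maltodextrin",
                        "monosodium glutamate", "sodium benzoate",
                        "natural flavours", "guar gum", "carrageenan",
                        "aspartame", "palm oil", "potassium sorbate"),
    blocks = blocks
  ), class = "synth_config")
}

validate_synth_config <- function(config) {
  if (!is.list(config) || is.null(config$blocks)) {
    stop("invalid synthetic config: no blocks", call. = FALSE)
  }
  for (i in seq_along(config$blocks)) {
    b <- config$blocks[[i]]
    at <- function(field) paste0("blocks[[", i, "]]$", field)
    if (is.null(b$subcategory) || !nzchar(b$subcategory)) {
      stop("invalid synthetic config at ", at("subcategory"), call. = FALSE)
    }
    if (is.null(b$n) || b$n < 0) {
      stop("invalid synthetic config at ", at("n"), ": n must be >= 0",
           call. = FALSE)
    }
    mix <- b$nova_mix
    if (is.null(mix) || any(mix < 0) || any(mix > 1) ||
        abs(sum(mix) - 1) > 1e-8 ||
        !all(names(mix) %in% nova_groups)) {
      stop("invalid synthetic config at ", at("nova_mix"),
           ": probabilities over NOVA1..NOVA4 summing to 1", call. = FALSE)
    }
    if (("NOVA2" %in% names(mix)) && mix[["NOVA2"]] > 0 &&
        length(b$nova2_terms) == 0) {
      stop("invalid synthetic config at ", at("nova2_terms"),
           ": blocks generating NOVA2 need culinary substance terms",
           call. = FALSE)
    }
    if (length(b$base_tokens) == 0) {
      stop("invalid synthetic config at ", at("base_tokens"), call. = FALSE)
    }
    for (p in c("p_missing_neg", "p_missing_pos", "p_composite", "p_imitation")) {
      if (!is.null(b[[p]]) && (b[[p]] < 0 || b[[p]] > 1)) {
        stop("invalid synthetic config at ", at(p), ": probability in [0,1]",
             call. = FALSE)
      }
    }
  }
  invisible(config)
}

# independent, order-robust RNG stream per block
block_seed <- function(seed, name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% 1000003
  as.integer(((seed %% 2039) * 1000003 + h) %% 2147483647)
}

# draw n values from a {fixed} or {median, dispersion} log-normal spec
gen_values <- function(spec, n, upper = Inf) {
  if (is.null(spec)) return(rep(NA_real_, n))
  if (!is.null(spec$fixed)) return(rep(spec$fixed, n))
  v <- stats::rlnorm(n, meanlog = log(spec$median), sdlog = spec$dispersion)
  pmin(v, upper)
}

#' Generate a synthetic branded-food database with ground truth
#'
#' Fully deterministic given the seed. Returns the food table together with
#' a ground-truth table holding each product's intended NOVA group, intended
#' tier under both default pyramids (`NA` when flagged or pyramid-
#' ineligible), and the generated nutrient values before missingness masks.
#' The truth table is never embedded in the food table, so the pipeline
#' cannot see its labels.
#'
#' @param config A `synth_config` (see [default_synth_config()]).
#' @param seed Integer seed; defaults to the config's.
#' @param distractors Add lexicon-disjoint distractor tokens to NOVA1/3/4
#'   ingredient texts (never to NOVA2, whose single-substance rule they
#'   would break).
#' @return List with `foods` (food table) and `truth`.
#' @export
generate_food_db <- function(config = default_synth_config(),
                             seed = config$seed, distractors = TRUE) {
  validate_synth_config(config)
  tmdp <- default_pyramid_mapping("tmdp")
  smdp <- default_pyramid_mapping("smdp")
  out_foods <- list()
  out_truth <- list()
  for (bi in seq_along(config$blocks)) {
    b <- config$blocks[[bi]]
    if (b$n == 0) next
    set.seed(block_seed(seed, b$subcategory))
    n <- b$n
    groups <- sample(names(b$nova_mix), n, replace = TRUE, prob = b$nova_mix)
    energy <- round(gen_values(b$nutrients$energy_kcal, n), 0)
    protein <- round(gen_values(b$nutrients$protein_g, n), 2)
    fat <- round(gen_values(b$nutrients$total_fat_g, n), 2)
    sfa <- round(fat * stats::runif(n, b$sfa_frac[1], b$sfa_frac[2]), 2)
    sugars <- round(gen_values(b$nutrients$sugars_g, n, upper = 100), 2)
    salt <- round(gen_values(b$nutrients$salt_g, n), 2)
    fiber <- round(gen_values(b$fiber, n), 2)
    fv <- round(pmin(gen_values(b$fv, n), 100), 1)
    text <- vapply(groups, function(g) {
      base <- sample(b$base_tokens, min(2, length(b$base_tokens)))
      tokens <- switch(g,
        NOVA1 = base,
        NOVA2 = sample(b$nova2_terms, 1),
        NOVA3 = c(base[1], sample(config$culinary_pool, 1)),
        NOVA4 = c(base[1], sample(config$upf_marker_pool,
                                  sample(1:2, 1)))
      )
      if (distractors && g != "NOVA2" &&
          stats::runif(1) < config$distractor_rate) {
        tokens <- c(tokens, sample(config$distractor_pool, sample(1:2, 1)))
      }
      paste(tokens, collapse = ", ")
    }, character(1))
    composite <- stats::runif(n) < (b$p_composite %||% 0)
    imitation <- !composite & stats::runif(n) < (b$p_imitation %||% 0)
    # missingness masks (negative nutrients can exclude a food from scoring,
    # positive nutrients are later imputed to zero)
    mask <- function(v, p) ifelse(stats::runif(n) < p, NA_real_, v)
    p_neg <- b$p_missing_neg %||% 0
    p_pos <- b$p_missing_pos %||% 0
    foods <- tibble::tibble(
      id = sprintf("b%02d-%04d", bi, seq_len(n)),
      name = paste(b$subcategory, "product", seq_len(n)),
      subcategory = b$subcategory,
      basis = b$basis,
      is_water = FALSE,
      is_composite_dish = composite,
      is_plant_based_imitation = imitation,
      ingredient_text = text,
      energy_kcal = mask(energy, p_neg),
      protein_g = mask(protein, p_pos),
      total_fat_g = fat,
      sfa_g = mask(sfa, p_neg),
      sugars_g = mask(sugars, p_neg),
      salt_g = mask(salt, p_neg),
      fiber_g = mask(fiber, p_pos),
      fv_percent = mask(fv, p_pos)
    )
    flagged <- composite | imitation
    truth <- tibble::tibble(
      id = foods$id,
      subcategory = b$subcategory,
      nova_true = groups,
      tier_tmdp = ifelse(flagged, NA_character_,
                         unname(tmdp$mapping[b$subcategory])),
      tier_smdp = ifelse(flagged, NA_character_,
                         unname(smdp$mapping[b$subcategory])),
      true_energy_kcal = energy, true_protein_g = protein,
      true_total_fat_g = fat, true_sfa_g = sfa, true_sugars_g = sugars,
      true_salt_g = salt, true_fiber_g = fiber, true_fv_percent = fv
    )
    out_foods[[bi]] <- foods
    out_truth[[bi]] <- truth
  }
  list(foods = dplyr::bind_rows(out_foods), truth = dplyr::bind_rows(out_truth))
}
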