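# Reporting tables: NOVA distributions, tier-by-NOVA cross-tabulations,
# nutrient and FSAm-NPS comparisons across NOVA groups with Kruskal-Wallis /
# Mann-Whitney tests and Bonferroni correction.
#
# Conventions shared by all builders: foods without a NOVA group
# (UNCLASSIFIABLE) are excluded from denominators; empty tier-by-NOVA cells
# are omitted; any comparison involving a group with fewer than two values
# is reported "n.a."; Bonferroni multiplies each pairwise p-value by the
# number of pairs tested within the same tier-by-variable family (capped
# at 1).

comparison_nutrients <- c("energy_kcal", "protein_g", "total_fat_g",
                          "sfa_g", "sugars_g", "salt_g")
nova_pairs <- list(c("NOVA1", "NOVA4"), c("NOVA3", "NOVA4"))

#' NOVA distribution per analysis scope
#'
#' Counts and percentages of the four NOVA groups for the whole database and
#' for each set of pyramid-eligible foods, mirroring a market-level
#' distribution table. Unclassifiable foods are excluded from every
#' denominator.
#'
#' @param nova NOVA assignments ([classify_all()] output).
#' @param tiers Named list of tier-assignment tables ([assign_tiers()]
#'   output); each contributes a scope restricted to its assigned foods.
#' @return Tibble: `scope`, `scope_n`, `group`, `n`, `pct`.
#' @export
nova_distribution_table <- function(nova, tiers = list()) {
  classified <- nova[nova$group %in% nova_groups, c("id", "group")]
  scopes <- c(list("All foods" = classified$id),
              lapply(tiers, function(t) t$id[t$status == "assigned"]))
  purrr::imap_dfr(scopes, function(ids, scope) {
    sub <- classified[classified$id %in% ids, ]
    counts <- table(factor(sub$group, levels = nova_groups))
    n_scope <- sum(counts)
    tibble::tibble(
      scope = scope, scope_n = n_scope,
      group = nova_groups, n = as.integer(counts),
      pct = if (n_scope > 0) 100 * as.integer(counts) / n_scope else 0
    )
  })
}

#' Tier-by-NOVA cross-tabulation
#'
#' Counts and row percentages of NOVA groups per pyramid tier (optionally per
#' tier-by-subcategory). Only assigned, classified foods contribute; empty
#' combinations are omitted.
#'
#' @param foods Food table (used for the subcategory column).
#' @param nova NOVA assignments.
#' @param tiers One tier-assignment table.
#' @param by_subcategory Break rows down by food subcategory.
#' @return Tibble: `tier`, (`subcategory`,) `group`, `n`, `pct`, `row_n`.
#' @export
tier_nova_crosstab <- function(foods, nova, tiers, by_subcategory = FALSE) {
  df <- dplyr::inner_join(
    tiers[tiers$status == "assigned", c("id", "tier")],
    nova[nova$group %in% nova_groups, c("id", "group")],
    by = "id"
  )
  df <- dplyr::left_join(df, foods[, c("id", "subcategory")], by = "id")
  keys <- if (by_subcategory) c("tier", "subcategory") else "tier"
  out <- df |>
    dplyr::count(dplyr::across(dplyr::all_of(c(keys, "group")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(row_n = sum(.data$n), pct = 100 * .data$n / .data$row_n) |>
    dplyr::ungroup()
  out[, c(keys, "group", "n", "pct", "row_n")]
}

# Omnibus + pairwise-vs-NOVA4 tests for one tier x variable family.
# `values` is a named list: NOVA group -> numeric vector.
family_tests <- function(values, alpha) {
  eligible <- names(values)[vapply(values, function(v) sum(!is.na(v)) >= 2,
                                   logical(1))]
  rows <- list()
  # omnibus: Kruskal-Wallis for >= 3 eligible groups, Mann-Whitney for 2
  if (length(eligible) >= 3) {
    kw <- kruskal_wallis(values[eligible])
    rows[[1]] <- tibble::tibble(comparison = "omnibus", statistic = kw$H,
                                p = kw$p, p_adj = NA_real_)
  } else if (length(eligible) == 2) {
    mw <- mann_whitney_u(values[[eligible[1]]], values[[eligible[2]]])
    rows[[1]] <- tibble::tibble(comparison = "omnibus", statistic = mw$U,
                                p = mw$p, p_adj = NA_real_)
  } else {
    rows[[1]] <- tibble::tibble(comparison = "omnibus", statistic = NA_real_,
                                p = NA_real_, p_adj = NA_real_)
  }
  # pairwise vs NOVA4, Bonferroni over the pairs actually tested
  testable <- Filter(function(pair) all(pair %in% eligible), nova_pairs)
  n_pairs <- length(testable)
  pair_rows <- lapply(nova_pairs, function(pair) {
    label <- paste(pair, collapse = " vs ")
    if (!all(pair %in% eligible)) {
      return(tibble::tibble(comparison = label, statistic = NA_real_,
                            p = NA_real_, p_adj = NA_real_))
    }
    mw <- mann_whitney_u(values[[pair[1]]], values[[pair[2]]])
    tibble::tibble(comparison = label, statistic = mw$U, p = mw$p,
                   p_adj = min(mw$p * n_pairs, 1))
  })
  out <- dplyr::bind_rows(c(rows, pair_rows))
  out$significant <- !is.na(dplyr::coalesce(out$p_adj, out$p)) &
    dplyr::coalesce(out$p_adj, out$p) < alpha
  out$label <- ifelse(is.na(out$p), "n.a.",
                      formatC(dplyr::coalesce(out$p_adj, out$p),
                              digits = 3, format = "g"))
  out
}

# shared scaffolding: join value columns with tier + NOVA group
joined_cells <- function(values_df, nova, tiers) {
  df <- dplyr::inner_join(
    tiers[tiers$status == "assigned", c("id", "tier")],
    nova[nova$group %in% nova_groups, c("id", "group")],
    by = "id"
  )
  dplyr::inner_join(df, values_df, by = "id")
}

#' Nutrient comparison across NOVA groups per pyramid tier
#'
#' For every tier-by-NOVA cell: median and quartiles of energy, protein,
#' total fat, saturated fat, sugars and salt per 100 g/mL. For every
#' tier-by-nutrient family: an omnibus test (Kruskal-Wallis when at least
#' three groups have n >= 2, Mann-Whitney when exactly two) and pairwise
#' NOVA1-vs-NOVA4 / NOVA3-vs-NOVA4 Mann-Whitney tests with Bonferroni
#' correction; untestable comparisons are labelled `"n.a."`.
#'
#' @param foods Food table.
#' @param nova NOVA assignments.
#' @param tiers One tier-assignment table.
#' @param alpha Significance level for the flag (default 0.01).
#' @return List with `summary` (tibble `tier`, `group`, `nutrient`, `n`,
#'   `median`, `q1`, `q3`) and `tests` (tibble `tier`, `nutrient`,
#'   `comparison`, `statistic`, `p`, `p_adj`, `significant`, `label`).
#' @export
nutrient_comparison_table <- function(foods, nova, tiers, alpha = 0.01) {
  df <- joined_cells(foods[, c("id", comparison_nutrients)], nova, tiers)
  summary <- purrr::map_dfr(comparison_nutrients, function(nutrient) {
    df |>
      dplyr::group_by(.data$tier, .data$group) |>
      dplyr::summarise(
        nutrient = nutrient,
        n = sum(!is.na(.data[[nutrient]])),
        stats = list(if (sum(!is.na(.data[[nutrient]])) >= 1)
          median_iqr(.data[[nutrient]]) else c(median = NA_real_,
                                               q1 = NA_real_, q3 = NA_real_)),
        .groups = "drop"
      ) |>
      tidyr::unnest_wider("stats")
  })
  summary <- summary[order(summary$tier, summary$nutrient, summary$group),
                     c("tier", "group", "nutrient", "n", "median", "q1", "q3")]
  tests <- df |>
    dplyr::group_by(.data$tier) |>
    dplyr::group_modify(function(d, key) {
      purrr::map_dfr(comparison_nutrients, function(nutrient) {
        values <- split(d[[nutrient]], d$group)
        out <- family_tests(values, alpha)
        out$nutrient <- nutrient
        out
      })
    }) |>
    dplyr::ungroup()
  tests <- tests[, c("tier", "nutrient", "comparison", "statistic", "p",
                     "p_adj", "significant", "label")]
  list(summary = summary, tests = tests)
}

#' FSAm-NPS score and Nutri-Score grade distribution per tier and NOVA group
#'
#' For every tier-by-NOVA cell of scored foods: mean and SD of the FSAm-NPS
#' score (plus the median and quartiles), and counts with row percentages of
#' the Nutri-Score grades A-E. Testing of the score across NOVA groups uses
#' the same scheme as [nutrient_comparison_table()].
#'
#' @param scores Scoring results ([score_foods()] output); excluded foods
#'   are dropped.
#' @param nova NOVA assignments.
#' @param tiers One tier-assignment table.
#' @param alpha Significance level for the flag (default 0.01).
#' @return List with `summary` (tibble `tier`, `group`, `n`, `mean_score`,
#'   `sd_score`, `median`, `q1`, `q3`, `A_n` .. `E_n`, `A_pct` .. `E_pct`)
#'   and `tests` (as in [nutrient_comparison_table()], `nutrient = "score"`).
#' @export
nutriscore_distribution_table <- function(scores, nova, tiers, alpha = 0.01) {
  scored <- scores[scores$status == "scored", c("id", "score", "grade")]
  df <- joined_cells(scored, nova, tiers)
  summary <- df |>
    dplyr::group_by(.data$tier, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_score = mean(.data$score),
      sd_score = stats::sd(.data$score),
      stats = list(median_iqr(.data$score)),
      grades = list(table(factor(.data$grade, levels = c("A", "B", "C", "D", "E")))),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("stats")
  for (g in c("A", "B", "C", "D", "E")) {
    summary[[paste0(g, "_n")]] <- vapply(summary$grades, function(t)
      as.integer(t[[g]]), integer(1))
  }
  for (g in c("A", "B", "C", "D", "E")) {
    summary[[paste0(g, "_pct")]] <- 100 * summary[[paste0(g, "_n")]] / summary$n
  }
  summary$grades <- NULL
  tests <- df |>
    dplyr::group_by(.data$tier) |>
    dplyr::group_modify(function(d, key) {
      out <- family_tests(split(d$score, d$group), alpha)
      out$nutrient <- "score"
      out
    }) |>
    dplyr::ungroup()
  tests <- tests[, c("tier", "nutrient", "comparison", "statistic", "p",
                     "p_adj", "significant", "label")]
  list(summary = summary, tests = tests)
}

#' Run the full food-level analysis
#'
#' Convenience wrapper chaining the whole pipeline on one food table: NOVA
#' classification, FSAm-NPS scoring, tier assignment under both pyramids,
#' and every reporting table (NOVA distributions, tier and tier-by-
#' subcategory cross-tabulations for both pyramids, nutrient comparisons,
#' score/grade distributions, and the tier-level NOVA percentages), plus an
#' exclusion log.
#'
#' @param foods Food table.
#' @param lexicon A `nova_lexicon`.
#' @param tables A `score_tables` object.
#' @param mappings Named list with `tMDP` and `sMDP` `pyramid_mapping`s.
#' @param alpha Significance level (default 0.01).
#' @return Named list of assignments, scores and tables.
#' @export
run_food_analysis <- function(foods,
                              lexicon = default_lexicon(),
                              tables = default_score_tables(),
                              mappings = list(
                                tMDP = default_pyramid_mapping("tmdp"),
                                sMDP = default_pyramid_mapping("smdp")),
                              alpha = 0.01) {
  nova <- classify_all(foods, lexicon)
  scores <- score_foods(foods, tables)
  tiers <- lapply(mappings, function(m) assign_tiers(foods, m))
  exclusions <- tibble::tibble(
    reason = c("unclassifiable_no_ingredient_text", "excluded_missing_negative",
               paste0(names(tiers), ": excluded_imitation"),
               paste0(names(tiers), ": excluded_composite"),
               paste0(names(tiers), ": ineligible_modern")),
    n = c(sum(nova$group == "UNCLASSIFIABLE"),
          sum(scores$status == "excluded_missing_negative"),
          vapply(tiers, function(t) sum(t$status == "excluded_imitation"), integer(1)),
          vapply(tiers, function(t) sum(t$status == "excluded_composite"), integer(1)),
          vapply(tiers, function(t) sum(t$status == "ineligible_modern"), integer(1)))
  )
  list(
    nova = nova, scores = scores, tiers = tiers,
    nova_distribution = nova_distribution_table(nova, tiers),
    crosstab = lapply(tiers, function(t)
      tier_nova_crosstab(foods, nova, t, by_subcategory = TRUE)),
    tier_nova_pct = lapply(tiers, function(t)
      tier_nova_crosstab(foods, nova, t, by_subcategory = FALSE)),
    nutrient_comparison = lapply(tiers, function(t)
      nutrient_comparison_table(foods, nova, t, alpha)),
    nutriscore_distribution = lapply(tiers, function(t)
      nutriscore_distribution_table(scores, nova, t, alpha)),
    exclusions = exclusions
  )
}
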