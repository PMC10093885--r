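# FSAm-NPS nutrient-profiling score and five-scale Nutri-Score grade.
#
# Negative components (energy kJ, total sugars g, saturated fat g, sodium mg)
# score 0-10 points each; positive components (protein g, fiber g, FV%) score
# 0-5 each. Score S = N - P lies in [-15, 40]. A missing negative nutrient
# excludes the food from scoring; missing positive nutrients are imputed to
# zero. Grades: solids A <= -1, B 0-2, C 3-10, D 11-18, E 19-40; non-water
# beverages B <= 1, C 2-5, D 6-9, E 10-40; waters always A.

negative_components <- c("energy_kj", "sugars_g", "sfa_g", "sodium_mg")
positive_components <- c("protein_g", "fiber_g", "fv_percent")

#' Read FSAm-NPS component threshold tables
#'
#' Loads the per-basis threshold tables (YAML) used to convert nutrient
#' amounts into component points, and the scoring mode.
#'
#' @param path Path to a score-tables YAML file.
#' @param mode Override the file's scoring mode: `"paper_subtraction"`
#'   (plain S = N - P with every positive component capped at 5) or
#'   `"full_rule"` (official protein-counting restriction, see [fsam_nps()]).
#' @return A `score_tables` list with elements `mode`, `solid`, `beverage`.
#' @export
read_score_tables <- function(path, mode = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(mode)) cfg$mode <- mode
  cfg$mode <- match.arg(cfg$mode, c("paper_subtraction", "full_rule"))
  for (basis in c("solid", "beverage")) {
    for (comp in c(negative_components, positive_components)) {
      tab <- cfg[[basis]][[comp]]
      if (is.null(tab$thresholds)) {
        stop("score tables: missing thresholds for ", basis, "/", comp,
             call. = FALSE)
      }
      tab$thresholds <- as.numeric(tab$thresholds)
      tab$points <- if (is.null(tab$points)) {
        0:length(tab$thresholds)
      } else {
        as.numeric(tab$points)
      }
      check_thresholds(tab$thresholds, tab$points)
      cfg[[basis]][[comp]] <- tab
    }
  }
  structure(cfg[c("mode", "solid", "beverage")], class = "score_tables")
}

#' @rdname read_score_tables
#' @export
default_score_tables <- function(mode = NULL) {
  read_score_tables(novamed_extdata("fsamnps_tables.yaml"), mode = mode)
}

check_thresholds <- function(thresholds, points = 0:length(thresholds)) {
  if (length(thresholds) == 0 || any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  if (length(points) != length(thresholds) + 1L || any(diff(points) < 0)) {
    stop("points must be non-decreasing with one entry per band", call. = FALSE)
  }
  invisible(TRUE)
}

#' Component points for one nutrient amount
#'
#' Points equal the number of thresholds strictly below the value (boundary
#' values take the lower band), optionally mapped through an explicit band ->
#' points vector; monotone non-decreasing in the value.
#'
#' @param value Nutrient amount(s), >= 0.
#' @param thresholds Strictly increasing threshold vector.
#' @param points Optional points per band (length `length(thresholds) + 1`);
#'   defaults to `0:length(thresholds)`.
#' @return Numeric vector of points.
#' @export
#' @examples
#' component_points(192.464, c(335, 670, 1005)) # 0
component_points <- function(value, thresholds,
                             points = 0:length(thresholds)) {
  check_thresholds(thresholds, points)
  points <- as.numeric(points)
  if (any(value < 0, na.rm = TRUE)) stop("value must be >= 0", call. = FALSE)
  band <- vapply(value, function(v) {
    if (is.na(v)) NA_integer_ else sum(v > thresholds)
  }, integer(1))
  points[band + 1L]
}

# panel -> named points for the four negative components (kcal and salt are
# converted to the kJ / sodium-mg scales first)
negative_breakdown <- function(panel, basis, tables) {
  values <- c(
    energy_kj = kcal_to_kj(panel$energy_kcal),
    sugars_g = panel$sugars_g,
    sfa_g = panel$sfa_g,
    sodium_mg = salt_to_sodium_mg(panel$salt_g)
  )
  vapply(negative_components, function(comp) {
    tab <- tables[[basis]][[comp]]
    component_points(values[[comp]], tab$thresholds, tab$points)
  }, numeric(1))
}

positive_breakdown <- function(panel, basis, tables, cap = 5) {
  pts <- vapply(positive_components, function(comp) {
    tab <- tables[[basis]][[comp]]
    component_points(panel[[comp]], tab$thresholds, tab$points)
  }, numeric(1))
  if (!is.null(cap)) pts <- pmin(pts, cap)
  pts
}

#' Negative-component point total
#'
#' @param panel Nutrient panel (named list/one-row tibble with `energy_kcal`,
#'   `sugars_g`, `sfa_g`, `salt_g`); all four must be present (non-`NA`).
#' @param basis `"solid"` or `"beverage"`.
#' @param tables A `score_tables` object.
#' @return List with `total` (0-40) and the per-component `breakdown`.
#' @export
negative_points <- function(panel, basis = "solid",
                            tables = default_score_tables()) {
  panel <- as.list(panel)
  missing <- negative_nutrients[vapply(
    negative_nutrients, function(f) is.null(panel[[f]]) || is.na(panel[[f]]),
    logical(1))]
  if (length(missing) > 0) {
    stop("missing negative nutrient(s): ", paste(missing, collapse = ", "),
         " (food must be excluded from scoring)", call. = FALSE)
  }
  breakdown <- negative_breakdown(panel, basis, tables)
  list(total = sum(breakdown), breakdown = breakdown)
}

#' Positive-component point total
#'
#' Missing positive nutrients must already be imputed to zero (done by
#' [fsam_nps()]). In `paper_subtraction` mode every component is capped at 5.
#'
#' @inheritParams negative_points
#' @return List with `total` (0-15) and the per-component `breakdown`.
#' @export
positive_points <- function(panel, basis = "solid",
                            tables = default_score_tables()) {
  panel <- as.list(panel)
  for (f in positive_nutrients) {
    if (is.null(panel[[f]]) || is.na(panel[[f]])) panel[[f]] <- 0
  }
  cap <- if (tables$mode == "paper_subtraction") 5 else NULL
  breakdown <- positive_breakdown(panel, basis, tables, cap = cap)
  list(total = sum(breakdown), breakdown = breakdown)
}

#' Nutri-Score grade from an FSAm-NPS score
#'
#' Waters are always graded A. Solids map -15..-1 to A, 0-2 to B, 3-10 to C,
#' 11-18 to D, 19-40 to E; non-water beverages map -15..1 to B, 2-5 to C,
#' 6-9 to D, 10-40 to E (no beverage other than water can be graded A).
#'
#' @param score Integer FSAm-NPS score(s) in -15..40.
#' @param basis `"solid"` or `"beverage"` (recycled).
#' @param is_water Logical (recycled): water products are graded A.
#' @return Character vector of grades A-E.
#' @export
#' @examples
#' nutriscore_grade(-4, "solid") # "A"
nutriscore_grade <- function(score, basis = "solid", is_water = FALSE) {
  if (any(score < -15 | score > 40, na.rm = TRUE)) {
    stop("score outside the attainable range [-15, 40]", call. = FALSE)
  }
  n <- length(score)
  basis <- rep_len(basis, n)
  is_water <- rep_len(is_water, n)
  solid_grade <- function(s) {
    if (s <= -1) "A" else if (s <= 2) "B" else if (s <= 10) "C"
    else if (s <= 18) "D" else "E"
  }
  beverage_grade <- function(s) {
    if (s <= 1) "B" else if (s <= 5) "C" else if (s <= 9) "D" else "E"
  }
  vapply(seq_len(n), function(i) {
    if (is.na(score[i])) return(NA_character_)
    if (isTRUE(is_water[i])) return("A")
    if (basis[i] == "beverage") beverage_grade(score[i]) else solid_grade(score[i])
  }, character(1))
}

#' FSAm-NPS score and Nutri-Score grade for one food
#'
#' Applies the missing-data rules: a food missing any negative nutrient
#' (energy, sugars, saturated fat, salt) is excluded from scoring
#' (`status = "excluded_missing_negative"`); missing positive nutrients
#' (protein, fiber, FV%) are imputed to zero and recorded in
#' `imputed_fields`. In `full_rule` mode, protein points are not counted
#' when the negative total is >= 11, unless the FV component is at its
#' maximum or the food's subcategory is `"Cheese"`.
#'
#' @param food A single food (one-row tibble or named list; needs the
#'   nutrient panel plus `basis` and `is_water`; `id` and `subcategory` are
#'   used when present).
#' @param tables A `score_tables` object.
#' @return One-row tibble: `id`, `status`, per-component points, `n_points`,
#'   `p_points`, `score`, `grade`, `imputed_fields` (comma-separated).
#' @export
#' @examples
#' egg <- list(id = "egg", basis = "solid", energy_kcal = 46, protein_g = 11,
#'             total_fat_g = 0.3, sfa_g = 0, sugars_g = 0.3, salt_g = 0.44)
#' fsam_nps(egg)$score # -4
fsam_nps <- function(food, tables = default_score_tables()) {
  if (is.data.frame(food)) {
    stopifnot(nrow(food) == 1)
    food <- as.list(food)
  }
  id <- if (!is.null(food$id)) as.character(food$id) else NA_character_
  basis <- if (!is.null(food$basis) && !is.na(food$basis)) food$basis else "solid"
  is_water <- isTRUE(food$is_water)
  empty_row <- function(status) {
    tibble::tibble(
      id = id, status = status,
      energy_pts = NA_real_, sugars_pts = NA_real_, sfa_pts = NA_real_,
      sodium_pts = NA_real_, n_points = NA_real_,
      protein_pts = NA_real_, fiber_pts = NA_real_, fv_pts = NA_real_,
      p_points = NA_real_, score = NA_real_, grade = NA_character_,
      imputed_fields = NA_character_
    )
  }
  missing_neg <- negative_nutrients[vapply(
    negative_nutrients, function(f) is.null(food[[f]]) || is.na(food[[f]]),
    logical(1))]
  if (length(missing_neg) > 0) return(empty_row("excluded_missing_negative"))

  imputed <- positive_nutrients[vapply(
    positive_nutrients, function(f) is.null(food[[f]]) || is.na(food[[f]]),
    logical(1))]
  for (f in imputed) food[[f]] <- 0

  neg <- negative_breakdown(food, basis, tables)
  cap <- if (tables$mode == "paper_subtraction") 5 else NULL
  pos <- positive_breakdown(food, basis, tables, cap = cap)
  if (tables$mode == "full_rule") {
    fv_max <- max(tables[[basis]]$fv_percent$points)
    is_cheese <- identical(food$subcategory, "Cheese")
    if (sum(neg) >= 11 && pos[["fv_percent"]] < fv_max && !is_cheese) {
      pos[["protein_g"]] <- 0
    }
  }
  n_total <- sum(neg)
  p_total <- sum(pos)
  score <- n_total - p_total
  tibble::tibble(
    id = id, status = "scored",
    energy_pts = neg[["energy_kj"]], sugars_pts = neg[["sugars_g"]],
    sfa_pts = neg[["sfa_g"]], sodium_pts = neg[["sodium_mg"]],
    n_points = n_total,
    protein_pts = pos[["protein_g"]], fiber_pts = pos[["fiber_g"]],
    fv_pts = pos[["fv_percent"]], p_points = p_total,
    score = score,
    grade = nutriscore_grade(score, basis, is_water),
    imputed_fields = paste(imputed, collapse = ",")
  )
}

#' Score every food of a table
#'
#' Applies [fsam_nps()] independently to each row, preserving order.
#'
#' @param foods Food table.
#' @param tables A `score_tables` object.
#' @return Tibble with one row per food (see [fsam_nps()]).
#' @export
score_foods <- function(foods, tables = default_score_tables()) {
  if (nrow(foods) == 0) {
    out <- fsam_nps(list(id = "x", basis = "solid", energy_kcal = 0,
                         sugars_g = 0, sfa_g = 0, salt_g = 0), tables)
    return(out[0, ])
  }
  purrr::map_dfr(seq_len(nrow(foods)), function(i) {
    fsam_nps(as.list(foods[i, ]), tables)
  })
}
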