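# Mediterranean-diet pyramid eligibility and tier assignment.
#
# Assignment is keyed on subcategory plus flags only; nutrient content and
# NOVA group never affect eligibility. Precedence: plant-based imitations are
# excluded from both pyramids, then composite traditional dishes, then
# subcategories absent from the mapping are modern (ineligible) foods;
# everything else is assigned its mapped tier.

#' Read a pyramid mapping
#'
#' Loads a pyramid config (YAML): pyramid name, tier list in base-to-top
#' order with consumption-frequency tags, the subcategory-to-tier map, and
#' optional alternative tiers selectable per food via a `tier_hint` column.
#'
#' @param path Path to a mapping YAML file.
#' @return A `pyramid_mapping` list with elements `pyramid`, `tiers`,
#'   `frequency`, `mapping` (named character vector) and `alternatives`.
#' @export
read_pyramid_mapping <- function(path) {
  cfg <- yaml::read_yaml(path)
  mapping <- unlist(cfg$mapping)
  out <- structure(list(
    pyramid = cfg$pyramid,
    tiers = as.character(cfg$tiers),
    frequency = unlist(cfg$frequency),
    mapping = mapping,
    alternatives = lapply(cfg$alternatives, as.character)
  ), class = "pyramid_mapping")
  validate_pyramid_mapping(out)
  out
}

#' @rdname read_pyramid_mapping
#' @param pyramid `"tmdp"` (traditional) or `"smdp"` (sustainable).
#' @export
default_pyramid_mapping <- function(pyramid = c("tmdp", "smdp")) {
  pyramid <- match.arg(pyramid)
  read_pyramid_mapping(novamed_extdata(paste0("pyramid_", pyramid, ".yaml")))
}

validate_pyramid_mapping <- function(mapping) {
  if (!is.list(mapping) || is.null(mapping$tiers) || is.null(mapping$mapping)) {
    stop("invalid pyramid mapping: expected tiers and mapping", call. = FALSE)
  }
  if (anyDuplicated(mapping$tiers)) {
    stop("invalid pyramid mapping: duplicated tier names", call. = FALSE)
  }
  bad <- setdiff(unique(mapping$mapping), mapping$tiers)
  if (length(bad) > 0) {
    stop("invalid pyramid mapping: mapped tier(s) not in the tier list: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad_alt <- setdiff(unique(unlist(mapping$alternatives)), mapping$tiers)
  if (length(bad_alt) > 0) {
    stop("invalid pyramid mapping: alternative tier(s) not in the tier list: ",
         paste(bad_alt, collapse = ", "), call. = FALSE)
  }
  invisible(mapping)
}

#' Assign one food to a pyramid tier
#'
#' Returns the food's eligibility status for the pyramid and, when eligible,
#' its tier. Statuses: `excluded_imitation` (plant-based meat/dairy
#' imitation), `excluded_composite` (composite traditional dish),
#' `ineligible_modern` (subcategory not described by any tier of this
#' pyramid), `assigned`. An optional `tier_hint` naming one of the
#' subcategory's alternative tiers overrides the primary tier.
#'
#' @param food A single food (one-row tibble or named list with
#'   `subcategory` and the exclusion flags; optional `tier_hint`).
#' @param mapping A `pyramid_mapping`.
#' @return One-row tibble: `id`, `pyramid`, `status`, `tier` (`NA` unless
#'   `status == "assigned"`).
#' @export
#' @examples
#' assign_tier(list(id = "p1", subcategory = "Pulses"),
#'             default_pyramid_mapping("tmdp"))
assign_tier <- function(food, mapping = default_pyramid_mapping("tmdp")) {
  if (is.data.frame(food)) {
    stopifnot(nrow(food) == 1)
    food <- as.list(food)
  }
  out <- assign_tiers(as_food_row(food), mapping)
  out
}

#' Assign every food of a table to a pyramid tier
#'
#' Vectorised [assign_tier()]: per-food, order-preserving, independent across
#' rows.
#'
#' @param foods Food table.
#' @param mapping A `pyramid_mapping`.
#' @return Tibble with one row per food: `id`, `pyramid`, `status`, `tier`.
#' @export
assign_tiers <- function(foods, mapping = default_pyramid_mapping("tmdp")) {
  validate_pyramid_mapping(mapping)
  n <- nrow(foods)
  tier <- unname(mapping$mapping[foods$subcategory])
  status <- ifelse(is.na(tier), "ineligible_modern", "assigned")
  # per-food alternative-tier hints
  if ("tier_hint" %in% names(foods)) {
    for (i in which(!is.na(foods$tier_hint))) {
      alts <- mapping$alternatives[[foods$subcategory[i]]]
      if (!is.na(tier[i]) && foods$tier_hint[i] %in% alts) {
        tier[i] <- foods$tier_hint[i]
      }
    }
  }
  composite <- !is.na(foods$is_composite_dish) & foods$is_composite_dish
  imitation <- !is.na(foods$is_plant_based_imitation) & foods$is_plant_based_imitation
  status[composite] <- "excluded_composite"
  status[imitation] <- "excluded_imitation"
  tier[status != "assigned"] <- NA_character_
  tibble::tibble(
    id = foods$id, pyramid = rep(mapping$pyramid, n),
    status = status, tier = tier
  )
}
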