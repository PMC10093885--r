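# Branded-food data model: schema, validation, unit conversions, CSV/JSON I/O.
#
# A food table is a tibble with one row per product. Missing nutrient values
# are NA and are semantically distinct from zero: a missing "negative"
# nutrient later excludes the product from FSAm-NPS scoring, a missing
# "positive" nutrient is imputed to zero.

# canonical column order and types of the branded-food table
food_table_columns <- c(
  "id", "name", "subcategory", "basis",
  "is_water", "is_composite_dish", "is_plant_based_imitation",
  "ingredient_text",
  "energy_kcal", "protein_g", "total_fat_g", "sfa_g", "sugars_g", "salt_g",
  "fiber_g", "fv_percent"
)
character_columns <- c("id", "name", "subcategory", "basis", "ingredient_text")
flag_columns <- c("is_water", "is_composite_dish", "is_plant_based_imitation")
nutrient_columns <- c(
  "energy_kcal", "protein_g", "total_fat_g", "sfa_g", "sugars_g", "salt_g",
  "fiber_g", "fv_percent"
)
negative_nutrients <- c("energy_kcal", "sugars_g", "sfa_g", "salt_g")
positive_nutrients <- c("protein_g", "fiber_g", "fv_percent")

#' Default subcategory vocabulary
#'
#' Returns the controlled vocabulary of food subcategories shipped with the
#' package: every subcategory mapped to a tier of the traditional or
#' sustainable Mediterranean-diet pyramid, plus a small set of modern
#' (pyramid-ineligible) packaged-food subcategories.
#'
#' @param path Path to a vocabulary YAML file; defaults to the shipped one.
#' @return Character vector of subcategory names.
#' @export
default_subcategories <- function(path = novamed_extdata("subcategories.yaml")) {
  cfg <- yaml::read_yaml(path)
  unique(c(cfg$mapped, cfg$unmapped))
}

#' Convert kilocalories to kilojoules
#'
#' The nutrition declaration carries energy in kcal while FSAm-NPS thresholds
#' are expressed in kJ; the thermochemical factor 4.184 kJ/kcal is used.
#'
#' @param e Energy in kcal (vectorised, values must be >= 0; NA passes through).
#' @return Energy in kJ.
#' @export
#' @examples
#' kcal_to_kj(46) # 192.464
kcal_to_kj <- function(e) {
  if (any(e < 0, na.rm = TRUE)) stop("energy must be >= 0", call. = FALSE)
  e * 4.184
}

#' Convert salt (g) to sodium (mg)
#'
#' EU labels declare salt while FSAm-NPS scores sodium; the EU convention
#' salt = sodium x 2.5 gives sodium_mg = salt_g * 400.
#'
#' @param salt Salt in g per 100 g/mL (vectorised, >= 0; NA passes through).
#' @return Sodium in mg per 100 g/mL.
#' @export
#' @examples
#' salt_to_sodium_mg(0.44) # 176
salt_to_sodium_mg <- function(salt) {
  if (any(salt < 0, na.rm = TRUE)) stop("salt must be >= 0", call. = FALSE)
  salt * 400
}

# one empty food table with the canonical schema
empty_food_table <- function() {
  tibble::tibble(
    id = character(), name = character(), subcategory = character(),
    basis = character(), is_water = logical(), is_composite_dish = logical(),
    is_plant_based_imitation = logical(), ingredient_text = character(),
    energy_kcal = double(), protein_g = double(), total_fat_g = double(),
    sfa_g = double(), sugars_g = double(), salt_g = double(),
    fiber_g = double(), fv_percent = double()
  )
}

coerce_food_table <- function(df) {
  missing_cols <- setdiff(food_table_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("food table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  for (col in character_columns) df[[col]] <- as.character(df[[col]])
  for (col in flag_columns) df[[col]] <- as.logical(df[[col]])
  for (col in nutrient_columns) df[[col]] <- as.numeric(df[[col]])
  extra <- setdiff(names(df), food_table_columns)
  df[, c(food_table_columns, extra)]
}

#' Validate a branded-food table
#'
#' Checks every invariant of the data model and reports each violation as one
#' row; validation never throws. Checked: non-empty unique ids, subcategory
#' in the vocabulary, basis in solid/beverage, water products declared as
#' beverages, non-negative nutrient values, saturated fat not exceeding total
#' fat, and sugars and fruit/vegetable percentage not exceeding 100.
#'
#' @param foods Food table (tibble with the canonical columns).
#' @param vocabulary Character vector of allowed subcategories.
#' @return Tibble with columns `id`, `field`, `problem`, `severity`
#'   (zero rows for a fully valid table).
#' @export
validate_foods <- function(foods, vocabulary = default_subcategories()) {
  foods <- coerce_food_table(foods)
  problems <- list()
  flag <- function(rows, field, problem, severity = "error") {
    if (!any(rows, na.rm = TRUE)) return()
    rows <- which(rows)
    problems[[length(problems) + 1L]] <<- tibble::tibble(
      id = foods$id[rows], field = field, problem = problem, severity = severity
    )
  }
  flag(is.na(foods$id) | !nzchar(foods$id), "id", "id is empty")
  flag(duplicated(foods$id) & !is.na(foods$id), "id", "id is duplicated")
  flag(!foods$subcategory %in% vocabulary, "subcategory",
       "subcategory not in the configured vocabulary")
  flag(!foods$basis %in% c("solid", "beverage"), "basis",
       "basis must be 'solid' or 'beverage'")
  flag(!is.na(foods$is_water) & foods$is_water & foods$basis != "beverage",
       "is_water", "water products must have basis 'beverage'")
  for (col in nutrient_columns) {
    flag(!is.na(foods[[col]]) & foods[[col]] < 0, col, "value must be >= 0")
  }
  flag(!is.na(foods$sfa_g) & !is.na(foods$total_fat_g) &
         foods$sfa_g > foods$total_fat_g,
       "sfa_g", "saturated fat exceeds total fat")
  flag(!is.na(foods$sugars_g) & foods$sugars_g > 100, "sugars_g",
       "sugars exceed 100 g per 100 g/mL")
  flag(!is.na(foods$fv_percent) & foods$fv_percent > 100, "fv_percent",
       "fruit/vegetable percentage exceeds 100")
  if (length(problems) == 0) {
    return(tibble::tibble(id = character(), field = character(),
                          problem = character(), severity = character()))
  }
  dplyr::bind_rows(problems)
}

#' @rdname validate_foods
#' @param food A single food (one-row tibble/data frame or named list).
#' @export
validate_food <- function(food, vocabulary = default_subcategories()) {
  validate_foods(as_food_row(food), vocabulary)
}

# accept a one-row data frame or a named list as a single food record
as_food_row <- function(food) {
  if (is.data.frame(food)) {
    if (nrow(food) != 1) stop("expected a single food record", call. = FALSE)
    df <- food
  } else {
    stopifnot(is.list(food))
    template <- as.list(empty_food_table()[1, ])
    template[] <- lapply(template, function(x) NA)
    template$is_water <- FALSE
    template$is_composite_dish <- FALSE
    template$is_plant_based_imitation <- FALSE
    template[names(food)] <- food
    df <- tibble::as_tibble(template)
  }
  coerce_food_table(df)
}

#' Read a branded-food table
#'
#' Reads a food table from CSV (one header row, empty cells for missing
#' values) or JSON (array of objects, `null` for missing values) and
#' validates it. Missing optional fields stay `NA` and are distinct from
#' zero. Numbers must use the period decimal separator; files are UTF-8.
#'
#' @param source Path to the file.
#' @param format `"csv"` or `"json"`; guessed from the file extension when
#'   omitted.
#' @param vocabulary Allowed subcategories (see [default_subcategories()]).
#' @param permissive If `TRUE`, validation problems are reported as a warning
#'   instead of an error (useful for unknown subcategories).
#' @return Tibble with one row per record, in file order.
#' @export
read_food_table <- function(source, format = c("auto", "csv", "json"),
                            vocabulary = default_subcategories(),
                            permissive = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", source, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    col_types <- do.call(readr::cols, c(
      stats::setNames(lapply(character_columns, function(x) readr::col_character()),
                      character_columns),
      stats::setNames(lapply(flag_columns, function(x) readr::col_logical()),
                      flag_columns),
      stats::setNames(lapply(nutrient_columns, function(x) readr::col_double()),
                      nutrient_columns),
      list(.default = readr::col_character())
    ))
    df <- readr::read_csv(source, col_types = col_types, na = "",
                          progress = FALSE)
    parse_problems <- readr::problems(df)
    if (nrow(parse_problems) > 0) {
      stop("malformed CSV at row(s) ",
           paste(utils::head(parse_problems$row, 5), collapse = ", "),
           ": ", parse_problems$expected[1], " expected, got '",
           parse_problems$actual[1], "'", call. = FALSE)
    }
  } else {
    df <- jsonlite::fromJSON(source, simplifyVector = TRUE)
    if (length(df) == 0) df <- empty_food_table()
    df <- tibble::as_tibble(df)
    # a fully-null JSON column arrives as logical NA; recoerce below
  }
  foods <- coerce_food_table(df)
  report <- validate_foods(foods, vocabulary)
  errors <- report[report$severity == "error", ]
  if (nrow(errors) > 0) {
    msg <- paste0(utils::head(
      paste0("record '", errors$id, "', field ", errors$field, ": ",
             errors$problem), 10), collapse = "\n  ")
    if (permissive) {
      warning("food table has validation problems:\n  ", msg, call. = FALSE)
    } else {
      stop("food table failed validation:\n  ", msg, call. = FALSE)
    }
  }
  foods
}

#' Write a branded-food table
#'
#' Inverse of [read_food_table()]: writes CSV (missing values as empty cells)
#' or JSON (missing values as `null`) so that a write/read round trip
#' reproduces the table field-for-field, including the distinction between
#' missing and zero.
#'
#' @param foods Food table.
#' @param sink Output file path.
#' @param format `"csv"` or `"json"`; guessed from the extension when omitted.
#' @return `sink`, invisibly.
#' @export
write_food_table <- function(foods, sink, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", sink, ignore.case = TRUE)) "json" else "csv"
  }
  foods <- coerce_food_table(foods)
  if (format == "csv") {
    readr::write_csv(foods, sink, na = "", progress = FALSE)
  } else {
    jsonlite::write_json(foods, sink, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(sink)
}
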