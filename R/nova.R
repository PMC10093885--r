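# NOVA classification from ingredient lists.
#
# The decision rule is ingredient-driven only (no subcategory overrides):
#   0. no/empty ingredient text            -> UNCLASSIFIABLE
#   1. >= 1 ultra-processing marker hit    -> NOVA4
#   2. a single culinary-substance token
#      (ignoring water)                    -> NOVA2
#   3. >= 1 culinary hit plus >= 1
#      non-culinary token                  -> NOVA3
#   4. otherwise                           -> NOVA1
# Precedence NOVA4 > NOVA2 > NOVA3 > NOVA1: any industrial additive forces
# NOVA4 regardless of the rest of the list.

nova_groups <- c("NOVA1", "NOVA2", "NOVA3", "NOVA4")
upf_categories <- c(
  "sweetener", "added_sodium", "added_oil", "protein_isolate", "flavor",
  "emulsifier", "thickener_bulking", "antioxidant_preservative",
  "fortificant", "other_industrial"
)

#' Read a NOVA marker lexicon
#'
#' Loads a lexicon config (YAML) holding ultra-processing marker terms with
#' category tags, culinary-ingredient terms, and the matching policy, and
#' validates it: both term sets non-empty, categories from the known set, and
#' no term in both sets.
#'
#' @param path Path to a lexicon YAML file.
#' @return A `nova_lexicon` list with elements `upf_markers` (tibble
#'   `term`/`category`), `culinary_terms` (character) and `matching_policy`.
#' @export
read_lexicon <- function(path) {
  cfg <- yaml::read_yaml(path)
  markers <- dplyr::bind_rows(lapply(cfg$upf_markers, tibble::as_tibble))
  lexicon <- structure(list(
    upf_markers = markers,
    culinary_terms = as.character(cfg$culinary_terms),
    matching_policy = list(
      case_fold = isTRUE(cfg$matching_policy$case_fold),
      word_boundary = isTRUE(cfg$matching_policy$word_boundary)
    )
  ), class = "nova_lexicon")
  validate_lexicon(lexicon)
  lexicon
}

#' @rdname read_lexicon
#' @export
default_lexicon <- function() {
  read_lexicon(novamed_extdata("nova_lexicon.yaml"))
}

validate_lexicon <- function(lexicon) {
  if (!is.list(lexicon) || is.null(lexicon$upf_markers) ||
      is.null(lexicon$culinary_terms)) {
    stop("invalid lexicon: expected upf_markers and culinary_terms",
         call. = FALSE)
  }
  markers <- lexicon$upf_markers
  if (nrow(markers) == 0 || length(lexicon$culinary_terms) == 0) {
    stop("invalid lexicon: term sets must be non-empty", call. = FALSE)
  }
  bad_cat <- setdiff(unique(markers$category), upf_categories)
  if (length(bad_cat) > 0) {
    stop("invalid lexicon: unknown marker category ",
         paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  overlap <- intersect(tolower(markers$term), tolower(lexicon$culinary_terms))
  if (length(overlap) > 0) {
    stop("invalid lexicon: term(s) in both upf_markers and culinary_terms: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  invisible(lexicon)
}

#' Normalise free-text ingredient lists into tokens
#'
#' Tokens are produced by case-folding, stripping percentage annotations and
#' bracketed quantities (e.g. `"(5%)"`, `"[30 g]"`), and splitting on
#' top-level commas and semicolons; sub-ingredients inside parentheses stay
#' attached to their parent token. Empty or absent text yields no tokens.
#'
#' @param text A single ingredient string (`NA` allowed).
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' normalize_ingredient_text("Sugar (5%), cocoa mass, emulsifier: soy lecithin")
normalize_ingredient_text <- function(text) {
  if (length(text) != 1) stop("expected a single string", call. = FALSE)
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(character(0))
  s <- tolower(text)
  # bracketed quantity/percentage annotations: (5%), (12.5 %), [30 g]
  s <- gsub("[(\\[]\\s*(approx\\.?\\s*)?[<>~]?\\s*\\d+([.,]\\d+)?\\s*(%|g|mg|kg|ml|l)?\\s*[)\\]]",
            "", s, perl = TRUE)
  # inline percentages: "sugar 5%" -> "sugar"
  s <- gsub("\\d+([.,]\\d+)?\\s*%", "", s, perl = TRUE)
  # split on commas/semicolons outside parentheses or brackets
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  token <- character(0)
  tokens <- character(0)
  for (ch in chars) {
    if (ch %in% c("(", "[")) depth <- depth + 1L
    if (ch %in% c(")", "]")) depth <- max(0L, depth - 1L)
    if (depth == 0L && ch %in% c(",", ";")) {
      tokens <- c(tokens, paste(token, collapse = ""))
      token <- character(0)
    } else {
      token <- c(token, ch)
    }
  }
  tokens <- c(tokens, paste(token, collapse = ""))
  tokens <- gsub("\\s+", " ", tokens)
  tokens <- gsub("^[ .]+|[ .]+$", "", tokens)
  tokens[nzchar(tokens)]
}

# regex for matching one lexicon term inside a token under the word-boundary
# policy; terms are escaped so they are matched literally
term_pattern <- function(term) {
  paste0("(^|[^[:alnum:]])",
         gsub("([][.\\\\|(){}^$*+?])", "\\\\\\1", term, perl = TRUE),
         "($|[^[:alnum:]])")
}

# which tokens does `term` match under the policy?
match_term <- function(term, tokens, policy) {
  if (length(tokens) == 0) return(logical(0))
  if (policy$case_fold) {
    term <- tolower(term)
    tokens <- tolower(tokens)
  }
  if (policy$word_boundary) {
    grepl(term_pattern(term), tokens, perl = TRUE)
  } else {
    tokens == term
  }
}

#' Detect ultra-processing markers in ingredient tokens
#'
#' Scans each token for every marker term of the lexicon under its matching
#' policy. The result is deterministic and independent of lexicon order: hits
#' are sorted by token position, then term.
#'
#' @param tokens Character vector of normalised ingredient tokens.
#' @param lexicon A `nova_lexicon` (see [default_lexicon()]).
#' @return Tibble with one row per (term, token) hit: columns `term`,
#'   `category`, `token`.
#' @export
detect_markers <- function(tokens, lexicon = default_lexicon()) {
  validate_lexicon(lexicon)
  empty <- tibble::tibble(term = character(), category = character(),
                          token = character())
  if (length(tokens) == 0) return(empty)
  markers <- lexicon$upf_markers
  hits <- lapply(seq_len(nrow(markers)), function(i) {
    hit <- match_term(markers$term[i], tokens, lexicon$matching_policy)
    if (!any(hit)) return(NULL)
    tibble::tibble(term = markers$term[i], category = markers$category[i],
                   token = tokens[hit], position = which(hit))
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0) return(empty)
  hits <- hits[order(hits$position, hits$term), ]
  hits$position <- NULL
  hits
}

# logical: does each token contain a culinary-ingredient term?
culinary_token <- function(tokens, lexicon) {
  if (length(tokens) == 0) return(logical(0))
  out <- rep(FALSE, length(tokens))
  for (term in lexicon$culinary_terms) {
    out <- out | match_term(term, tokens, lexicon$matching_policy)
  }
  out
}

#' Classify one food into a NOVA group
#'
#' Applies the ingredient-driven decision rule described in the package
#' vignette: any ultra-processing marker forces NOVA4; a single culinary
#' substance (optionally carried in water) is NOVA2; a culinary ingredient
#' added to other food tokens is NOVA3; anything else with a readable
#' ingredient list is NOVA1; foods without ingredient text are
#' UNCLASSIFIABLE.
#'
#' @param food A single food (one-row tibble or named list with at least
#'   `ingredient_text`; `id` is carried through when present).
#' @param lexicon A `nova_lexicon`.
#' @return One-row tibble: `id`, `group`, `rule_fired`, `matched_terms`
#'   (pipe-separated marker terms) and `hits` (list column holding the
#'   marker-evidence tibble).
#' @export
#' @examples
#' classify_nova(list(id = "x1", ingredient_text = "chickpeas"))
classify_nova <- function(food, lexicon = default_lexicon()) {
  validate_lexicon(lexicon)
  if (is.data.frame(food)) {
    stopifnot(nrow(food) == 1)
    food <- as.list(food)
  }
  id <- if (!is.null(food$id)) as.character(food$id) else NA_character_
  tokens <- normalize_ingredient_text(food$ingredient_text)
  hits <- detect_markers(tokens, lexicon)
  if (length(tokens) == 0) {
    group <- "UNCLASSIFIABLE"; rule <- "no_ingredient_text"
  } else if (nrow(hits) > 0) {
    group <- "NOVA4"; rule <- "upf_marker"
  } else {
    culinary <- culinary_token(tokens, lexicon)
    non_water <- tokens != "water"
    if (sum(non_water) == 1 && culinary[non_water]) {
      group <- "NOVA2"; rule <- "single_culinary_substance"
    } else if (any(culinary) && any(!culinary)) {
      group <- "NOVA3"; rule <- "culinary_added_to_food"
    } else {
      group <- "NOVA1"; rule <- "no_markers_no_culinary_addition"
    }
  }
  tibble::tibble(
    id = id, group = group, rule_fired = rule,
    matched_terms = paste(unique(hits$term), collapse = "|"),
    hits = list(hits)
  )
}

#' Classify every food of a table
#'
#' Applies [classify_nova()] independently to each row; order is preserved
#' and no record influences another.
#'
#' @param foods Food table (needs `id` and `ingredient_text` columns).
#' @param lexicon A `nova_lexicon`.
#' @return Tibble with one row per food (see [classify_nova()]).
#' @export
classify_all <- function(foods, lexicon = default_lexicon()) {
  validate_lexicon(lexicon)
  if (nrow(foods) == 0) {
    return(tibble::tibble(id = character(), group = character(),
                          rule_fired = character(), matched_terms = character(),
                          hits = list()))
  }
  purrr::map_dfr(seq_len(nrow(foods)), function(i) {
    classify_nova(list(id = foods$id[i],
                       ingredient_text = foods$ingredient_text[i]), lexicon)
  })
}
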