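#' Reference table of the 12 study foods and their B12 content
#'
#' Returns the fixed food reference used throughout the package: the twelve
#' food types tracked in recipe searches, their vitamin B12 content
#' (mcg per 100 g, NIH Office of Dietary Supplements values) and a unit cost
#' per serving used for the cost-weighted regional validation. Tomatoes carry
#' a B12 content of zero and act as the negligible-B12 negative control.
#'
#' The row order of this table is the canonical food order: every count
#' vector, coefficient vector and content vector in the package is aligned
#' to it.
#'
#' @param overrides Optional named numeric vector of B12 contents
#'   (mcg/100 g) replacing the defaults for the named foods. Names must be
#'   among the 12 known foods.
#' @return A tibble with columns `food`, `b12_mcg_100g`, `unit_cost`.
#' @examples
#' food_reference()
#' food_reference(overrides = c(beef = 0))
#' @export
food_reference <- function(overrides = NULL) {
  foods <- tibble::tibble(
    food = c(
      "shellfish", "mackerel", "beef", "trout", "salmon", "tuna",
      "milk", "turkey", "egg", "pork", "chicken", "tomato"
    ),
    b12_mcg_100g = c(98.9, 19, 6, 3.8, 2.4, 1.6, 0.9, 0.8, 0.6, 0.4, 0.3, 0),
    unit_cost = c(3.5, 2.2, 2.8, 3.0, 3.2, 1.5, 0.6, 1.9, 0.35, 2.0, 1.6, 0.5)
  )
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("`overrides` must be a named numeric vector of B12 contents.")
    }
    unknown <- setdiff(names(overrides), foods$food)
    if (length(unknown) > 0) {
      stop(
        "Unknown food name(s) in `overrides`: ",
        paste(unknown, collapse = ", ")
      )
    }
    idx <- match(names(overrides), foods$food)
    foods$b12_mcg_100g[idx] <- unname(overrides)
    if (any(foods$b12_mcg_100g < 0)) stop("B12 contents must be nonnegative.")
  }
  foods
}

#' Canonical food order
#'
#' @param foods A food reference table, as from [food_reference()].
#' @return Character vector of the 12 food names in canonical order.
#' @keywords internal
food_order <- function(foods = food_reference()) foods$food

#' Default mapping from foods to expenditure-survey categories
#'
#' The regional validation compares cost-weighted recipe-query fractions
#' against consumer-expenditure spending fractions for six aggregate food
#' categories: beef, pork, poultry (chicken + turkey), fish and seafood
#' (shellfish + mackerel + trout + salmon + tuna), eggs and milk. Tomatoes
#' have no expenditure category and are excluded from the validation.
#'
#' @return A tibble with columns `food`, `category`.
#' @export
default_category_mapping <- function() {
  tibble::tibble(
    food = c(
      "beef", "pork", "chicken", "turkey",
      "shellfish", "mackerel", "trout", "salmon", "tuna",
      "egg", "milk"
    ),
    category = c(
      "beef", "pork", "poultry", "poultry",
      "fish_seafood", "fish_seafood", "fish_seafood", "fish_seafood",
      "fish_seafood", "eggs", "milk"
    )
  )
}

#' Default medical-term lexicon
#'
#' A compact stand-in for the study term lists: 20 target terms (pain,
#' neuropathy and neuropsychiatric drugs and conditions hypothesised to be
#' linked to low B12 intake) and 20 control terms (common drugs and
#' conditions with no plausible B12 link, as an alphabetical-dictionary
#' sample would give). `is_drug` marks terms that are medicines and can be
#' joined against a drug-indication table; condition terms (e.g.
#' "neuropathy", "sinusitis") are not drugs.
#'
#' Term lists are configuration: analyses accept any lexicon with columns
#' `term`, `set` (one of `"target"`, `"control"`) and `is_drug`.
#'
#' @return A tibble with columns `term`, `set`, `is_drug`.
#' @export
default_term_lexicon <- function() {
  target <- tibble::tibble(
    term = c(
      "gabapentin", "tramadol", "neuropathy", "omeprazole", "sertraline",
      "citalopram", "oxycodone", "duloxetine", "trazodone", "pregabalin",
      "amitriptyline", "nortriptyline", "venlafaxine", "fibromyalgia",
      "paresthesia", "hydrocodone", "naproxen", "ranitidine", "cymbalta",
      "back pain"
    ),
    set = "target",
    is_drug = c(
      TRUE, TRUE, FALSE, TRUE, TRUE,
      TRUE, TRUE, TRUE, TRUE, TRUE,
      TRUE, TRUE, TRUE, FALSE,
      FALSE, TRUE, TRUE, TRUE, TRUE,
      FALSE
    )
  )
  control <- tibble::tibble(
    term = c(
      "amoxicillin", "metformin", "lisinopril", "atorvastatin",
      "levothyroxine", "albuterol", "warfarin", "insulin", "losartan",
      "azithromycin", "amlodipine", "simvastatin", "prednisone",
      "doxycycline", "clindamycin", "hydrochlorothiazide",
      "conjunctivitis", "eczema", "sinusitis", "bronchitis"
    ),
    set = "control",
    is_drug = c(rep(TRUE, 16), rep(FALSE, 4))
  )
  dplyr::bind_rows(target, control)
}

# column name used for a term's ask flag in a user profile table
term_column <- function(term) paste0("ask_", gsub("[^a-z0-9]+", "_", tolower(term)))
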