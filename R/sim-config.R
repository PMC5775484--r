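#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic search-log
#' generator. The generator emulates one month of food-recipe, medical-term
#' and B12-related searches by a population of users, with a configurable
#' negative dependence of symptom-term searching on each user's latent B12
#' intake, so that every analysis stage can be tested by parameter recovery.
#'
#' Defaults encode the package's reference study conditions: 50,000 users
#' (a desk-scale stand-in for the original multi-million-user population),
#' a 9449-recipe corpus, 20 target terms with per-mcg intake effects spread
#' over -0.08 to -0.02 on the log-odds scale and 20 null control terms,
#' per-term baseline ask rates between 0.8% and 8%, a 1% rate of B12-
#' deficiency awareness, and supplement-query conditionals of 3.83% (aware)
#' vs 0.0253% (unaware).
#'
#' @param seed Integer seed; mandatory. All generator output is a pure
#'   function of (config, seed).
#' @param n_users Number of users.
#' @param n_recipes Number of recipes in the synthetic corpus.
#' @param lexicon Term lexicon (see [default_term_lexicon()]); used to
#'   default `term_effects` and `baseline_term_rates`.
#' @param mean_food_searches Mean recipe queries per user (Poisson).
#' @param diet_concentration Positive Dirichlet concentration multiplier for
#'   per-user diet preferences; small values give extreme diets, large values
#'   near-identical diets.
#' @param ingredient_weights Length-12 nonnegative weights over the foods,
#'   used both as the recipe corpus ingredient weights and the Dirichlet base
#'   measure. Defaults to uniform.
#' @param term_effects Named numeric vector, term -> per-mcg shift in the
#'   log-odds of asking about the term (negative for target terms, 0 for
#'   controls).
#' @param baseline_term_rates Named numeric vector, term -> baseline ask
#'   probability at population-mean intake.
#' @param awareness_rate Probability that a user is aware of B12 deficiency.
#' @param awareness_intake_shift Nonpositive real; aware users' diet
#'   preference over food i is tilted by exp(shift * content_i), pushing them
#'   toward low-B12 foods.
#' @param supplement_given_awareness,supplement_given_no_awareness
#'   Probabilities of emitting a B12-supplement query conditional on
#'   awareness.
#' @param n_regions Number of region codes (0..n_regions-1).
#' @param expenditure_noise_sd Gaussian noise sd added to the synthetic
#'   expenditure fractions before renormalization.
#' @param indication_params List controlling the synthetic drug-indication
#'   table: `base` (baseline mean indication count), `popularity_coupling`,
#'   `effect_coupling`, `pain_base` (baseline pain-indication share),
#'   `pain_effect_coupling`, `noise_sd`, and `couple` (logical switch; FALSE
#'   zeroes all couplings).
#' @param noise_queries_per_user Mean count of unrelated filler queries per
#'   user (Poisson).
#' @return A validated list of class `cob12_config`.
#' @export
sim_config <- function(seed,
                       n_users = 50000,
                       n_recipes = 9449,
                       lexicon = default_term_lexicon(),
                       mean_food_searches = 2,
                       diet_concentration = 1,
                       ingredient_weights = NULL,
                       term_effects = NULL,
                       baseline_term_rates = NULL,
                       awareness_rate = 0.01,
                       awareness_intake_shift = -0.05,
                       supplement_given_awareness = 0.0383,
                       supplement_given_no_awareness = 0.000253,
                       n_regions = 4,
                       expenditure_noise_sd = 0.05,
                       indication_params = list(),
                       noise_queries_per_user = 1) {
  if (missing(seed)) stop("`seed` is mandatory.")
  stopifnot(
    is.numeric(seed), length(seed) == 1, !is.na(seed),
    n_users >= 1, n_recipes >= 1, n_regions >= 1,
    mean_food_searches >= 0, diet_concentration > 0,
    expenditure_noise_sd >= 0, noise_queries_per_user >= 0
  )
  if (awareness_intake_shift > 0) {
    stop("`awareness_intake_shift` must be <= 0.")
  }
  probs <- c(
    awareness_rate, supplement_given_awareness, supplement_given_no_awareness
  )
  if (any(probs < 0 | probs > 1)) stop("Probabilities must lie in [0, 1].")

  stopifnot(is.data.frame(lexicon), all(c("term", "set") %in% names(lexicon)))
  lexicon$term <- normalize_text(lexicon$term)
  if (anyDuplicated(lexicon$term)) stop("Lexicon terms must be unique.")
  if (!"is_drug" %in% names(lexicon)) lexicon$is_drug <- TRUE

  foods <- food_reference()
  if (is.null(ingredient_weights)) {
    ingredient_weights <- stats::setNames(rep(1 / 12, 12), foods$food)
  }
  stopifnot(
    length(ingredient_weights) == 12, all(ingredient_weights >= 0),
    sum(ingredient_weights) > 0
  )
  if (is.null(names(ingredient_weights))) {
    names(ingredient_weights) <- foods$food
  }
  stopifnot(setequal(names(ingredient_weights), foods$food))
  ingredient_weights <- ingredient_weights[foods$food]
  ingredient_weights <- ingredient_weights / sum(ingredient_weights)

  if (is.null(term_effects)) {
    term_effects <- default_term_effects(lexicon)
  }
  if (is.null(baseline_term_rates)) {
    baseline_term_rates <- default_baseline_rates(lexicon)
  }
  names(term_effects) <- normalize_text(names(term_effects))
  names(baseline_term_rates) <- normalize_text(names(baseline_term_rates))
  missing_eff <- setdiff(lexicon$term, names(term_effects))
  if (length(missing_eff) > 0) {
    stop("`term_effects` missing terms: ", paste(missing_eff, collapse = ", "))
  }
  missing_base <- setdiff(lexicon$term, names(baseline_term_rates))
  if (length(missing_base) > 0) {
    stop(
      "`baseline_term_rates` missing terms: ",
      paste(missing_base, collapse = ", ")
    )
  }
  base <- baseline_term_rates[lexicon$term]
  if (any(base <= 0 | base >= 1)) {
    stop("Baseline term rates must lie strictly inside (0, 1).")
  }

  ind_defaults <- list(
    base = 8, popularity_coupling = 0.5, effect_coupling = 1.0,
    pain_base = 0.3, pain_effect_coupling = 2.0, noise_sd = 0.3,
    couple = TRUE
  )
  indication_params <- utils::modifyList(ind_defaults, indication_params)

  structure(
    list(
      seed = as.integer(seed),
      n_users = as.integer(n_users),
      n_recipes = as.integer(n_recipes),
      lexicon = tibble::as_tibble(lexicon),
      mean_food_searches = mean_food_searches,
      diet_concentration = diet_concentration,
      ingredient_weights = ingredient_weights,
      term_effects = term_effects[lexicon$term],
      baseline_term_rates = base,
      awareness_rate = awareness_rate,
      awareness_intake_shift = awareness_intake_shift,
      supplement_given_awareness = supplement_given_awareness,
      supplement_given_no_awareness = supplement_given_no_awareness,
      n_regions = as.integer(n_regions),
      expenditure_noise_sd = expenditure_noise_sd,
      indication_params = indication_params,
      noise_queries_per_user = noise_queries_per_user
    ),
    class = "cob12_config"
  )
}

# targets get per-mcg log-odds effects spread over -0.08..-0.02 (in lexicon
# order), controls 0
default_term_effects <- function(lexicon) {
  eff <- stats::setNames(rep(0, nrow(lexicon)), lexicon$term)
  tgt <- lexicon$term[lexicon$set == "target"]
  if (length(tgt) == 1) {
    eff[tgt] <- -0.05
  } else if (length(tgt) > 1) {
    eff[tgt] <- seq(-0.08, -0.02, length.out = length(tgt))
  }
  eff
}

# baseline ask rates vary geometrically 0.008..0.08 within each set so term
# popularity has realistic spread
default_baseline_rates <- function(lexicon) {
  rates <- stats::setNames(rep(NA_real_, nrow(lexicon)), lexicon$term)
  for (s in unique(lexicon$set)) {
    trm <- lexicon$term[lexicon$set == s]
    if (length(trm) == 1) {
      rates[trm] <- 0.03
    } else {
      rates[trm] <- exp(seq(log(0.008), log(0.08), length.out = length(trm)))
    }
  }
  rates
}

#' @export
print.cob12_config <- function(x, ...) {
  cat("<cob12_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  users:", x$n_users, " recipes:", x$n_recipes,
      " regions:", x$n_regions, "\n")
  cat("  terms:", nrow(x$lexicon),
      sprintf("(%d target / %d control)",
              sum(x$lexicon$set == "target"),
              sum(x$lexicon$set == "control")), "\n")
  cat("  mean food searches/user:", x$mean_food_searches, "\n")
  invisible(x)
}
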