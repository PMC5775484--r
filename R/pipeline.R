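#' Run the full synthetic study end to end
#'
#' Convenience driver reproducing the whole analysis on synthetic data:
#' generates the corpus, log, expenditure and indication tables from a
#' configuration; aggregates the log into user profiles; applies the
#' minimum-askers term filter; computes consumption scores, awareness
#' contrasts, the supplement contingency and the regional validation; fits
#' the per-term models with CoB12; contrasts target and control sets; and
#' fits the indication correlations and the weighted rank-regression
#' meta-model.
#'
#' @param config A [sim_config()] object.
#' @param min_askers Minimum asker count for a term to enter the analysis.
#' @param top_k Top-k convention for term ranking and the set contrast.
#' @return A list with all stage outputs (`profiles`, `term_filter`,
#'   `contrasts`, `contingency`, `regional`, `results`, `top_terms`,
#'   `set_contrast`, `correlations`, `tomato`, `indication_cors`, `meta`),
#'   the generated data (`recipes`, `events`, `truth`, `expenditure`,
#'   `indications`) and a `report` (class `cob12_report`).
#' @export
run_study <- function(config, min_askers = 1000, top_k = 10) {
  stopifnot(inherits(config, "cob12_config"))
  foods <- food_reference()
  recipes <- simulate_recipes(config)
  sim <- simulate_search_log(config, recipes)
  truth_counts <- dplyr::inner_join(
    dplyr::select(sim$truth$users, "user_id", "region"),
    sim$truth$food_counts, by = "user_id"
  )
  expenditure <- simulate_expenditure(
    regional_cost_fractions(truth_counts, foods), config
  )
  indications <- simulate_indications(sim$truth$terms, config)

  profiles <- aggregate_users(sim$events, recipes, config$lexicon, foods)
  term_filter <- filter_terms(profiles, config$lexicon, min_askers)
  scored <- estimate_b12(profiles, foods)
  contrasts <- dplyr::bind_rows(
    contrast_by_flag(scored, "asked_b12"),
    contrast_by_flag(scored, "asked_deficiency")
  )
  contingency <- supplement_contrast(profiles)
  regional <- validate_regional(profiles, foods, expenditure)

  results <- fit_term_models(profiles, term_filter, foods)
  top_terms <- rank_terms(results, top_k)
  set_contrast <- contrast_sets(results, top_k)
  correlations <- popularity_correlations(results)
  tomato <- tomato_check(results, foods)

  drug_results <- dplyr::semi_join(results, indications, by = "term")
  indication_cors <- if (nrow(drug_results) >= 3) {
    indication_correlations(results, indications)
  }
  meta <- if (nrow(drug_results) >= 6) {
    fit_meta_model(results, indications)
  }

  report <- build_report(
    contrasts = contrasts, contingency = contingency, regional = regional,
    top_terms = top_terms, set_contrast = set_contrast,
    correlations = correlations, tomato = tomato,
    indication_cors = indication_cors, meta = meta, config = config
  )
  list(
    config = config, foods = foods, recipes = recipes,
    events = sim$events, truth = sim$truth,
    expenditure = expenditure, indications = indications,
    profiles = profiles, term_filter = term_filter, scored = scored,
    contrasts = contrasts, contingency = contingency, regional = regional,
    results = results, top_terms = top_terms, set_contrast = set_contrast,
    correlations = correlations, tomato = tomato,
    indication_cors = indication_cors, meta = meta, report = report
  )
}
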