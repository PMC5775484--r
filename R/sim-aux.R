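#' Regional cost-weighted food-category query fractions
#'
#' For each region, sums the per-user food counts, weights each food total
#' by its unit cost, aggregates foods into expenditure categories by the
#' mapping, and normalizes to spending-like fractions. This is the
#' query-side quantity that the regional expenditure validation correlates
#' with survey data, and also the base from which the synthetic expenditure
#' table is generated.
#'
#' @param counts A data frame with a `region` column and one count column
#'   per mapped food (user profiles from [aggregate_users()] work directly).
#' @param foods Food reference table with `unit_cost`.
#' @param mapping Food-to-category mapping, as [default_category_mapping()].
#' @return A tibble `region`, `category`, `fraction`; fractions sum to 1
#'   within each region. Regions with no recipe-matched queries are dropped
#'   with a message.
#' @export
regional_cost_fractions <- function(counts, foods,
                                    mapping = default_category_mapping()) {
  stopifnot(is.data.frame(counts), "region" %in% names(counts))
  miss <- setdiff(mapping$food, names(counts))
  if (length(miss) > 0) {
    stop("Missing food count column(s): ", paste(miss, collapse = ", "))
  }
  long <- counts |>
    dplyr::select("region", dplyr::all_of(mapping$food)) |>
    tidyr::pivot_longer(-"region", names_to = "food", values_to = "n") |>
    dplyr::group_by(.data$region, .data$food) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::inner_join(
      dplyr::select(foods, "food", "unit_cost"), by = "food"
    ) |>
    dplyr::inner_join(mapping, by = "food") |>
    dplyr::group_by(.data$region, .data$category) |>
    dplyr::summarise(w = sum(.data$n * .data$unit_cost), .groups = "drop")
  totals <- long |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(tot = sum(.data$w), .groups = "drop")
  empty <- totals$region[totals$tot == 0]
  if (length(empty) > 0) {
    message(
      "Excluding ", length(empty),
      " region(s) with no recipe-matched queries: ",
      paste(empty, collapse = ", ")
    )
  }
  long |>
    dplyr::inner_join(totals, by = "region") |>
    dplyr::filter(.data$tot > 0) |>
    dplyr::mutate(fraction = .data$w / .data$tot) |>
    dplyr::select("region", "category", "fraction") |>
    dplyr::arrange(.data$region, .data$category)
}

#' Generate a synthetic regional expenditure table
#'
#' Emulates a consumer-expenditure survey: takes true cost-weighted regional
#' query fractions, perturbs them with Gaussian noise of sd
#' `expenditure_noise_sd`, truncates at zero and renormalizes each region to
#' a simplex. With zero noise the table equals the input fractions, so the
#' downstream validation correlation is 1 by construction.
#'
#' @param fractions A tibble `region`, `category`, `fraction`, typically from
#'   [regional_cost_fractions()].
#' @param config A [sim_config()] object (supplies the seed and noise sd).
#' @return A tibble `region`, `category`, `fraction`.
#' @export
simulate_expenditure <- function(fractions, config) {
  stopifnot(inherits(config, "cob12_config"))
  stopifnot(all(c("region", "category", "fraction") %in% names(fractions)))
  if (length(unique(fractions$region)) < 2) {
    stop("Need at least 2 regions to build an expenditure table.")
  }
  with_seed_offset(config$seed, 303L, {
    out <- fractions
    out$fraction <- pmax(
      out$fraction + stats::rnorm(nrow(out), 0, config$expenditure_noise_sd),
      0
    )
    out |>
      dplyr::group_by(.data$region) |>
      dplyr::mutate(fraction = .data$fraction / sum(.data$fraction)) |>
      dplyr::ungroup()
  })
}

#' Generate a synthetic drug-indication table
#'
#' Emulates an adverse-reaction database extract giving, per drug, the
#' number of recorded indications and how many of those mention pain. When
#' coupling is on (`indication_params$couple`), indication counts increase
#' with term popularity (baseline ask rate) and with the magnitude of the
#' term's true intake effect, while the pain share decreases with that
#' magnitude — encoding the sign pattern the meta-model is expected to
#' recover (more indications, lower CoB12; larger pain share, higher
#' CoB12). With coupling off all couplings are zero and the table is pure
#' noise.
#'
#' @param terms A tibble of terms with columns `term`, `is_drug`, `effect`
#'   and `baseline` (the generator truth `terms` table).
#' @param config A [sim_config()] object.
#' @return A tibble `term`, `n_indications`, `n_pain_indications` covering
#'   the drug terms only.
#' @export
simulate_indications <- function(terms, config) {
  stopifnot(inherits(config, "cob12_config"))
  stopifnot(all(c("term", "is_drug", "effect", "baseline") %in% names(terms)))
  drugs <- dplyr::filter(terms, .data$is_drug)
  if (nrow(drugs) == 0) stop("No drug terms to generate indications for.")
  p <- config$indication_params
  k_pop <- if (isTRUE(p$couple)) p$popularity_coupling else 0
  k_eff <- if (isTRUE(p$couple)) p$effect_coupling else 0
  k_pain <- if (isTRUE(p$couple)) p$pain_effect_coupling else 0

  z_pop <- scale_or_zero(stats::qlogis(drugs$baseline))
  z_eff <- scale_or_zero(abs(drugs$effect))
  with_seed_offset(config$seed, 404L, {
    log_mu <- log(p$base) + k_pop * z_pop + k_eff * z_eff +
      stats::rnorm(nrow(drugs), 0, p$noise_sd)
    n_ind <- 1L + stats::rpois(nrow(drugs), exp(log_mu))
    pain_p <- stats::plogis(
      stats::qlogis(p$pain_base) - k_pain * z_eff +
        stats::rnorm(nrow(drugs), 0, p$noise_sd)
    )
    tibble::tibble(
      term = drugs$term,
      n_indications = n_ind,
      n_pain_indications = stats::rbinom(nrow(drugs), n_ind, pain_p)
    )
  })
}

# standardize, or all zeros when the input is constant
scale_or_zero <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
}
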