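#' Estimate per-user B12 consumption scores
#'
#' The consumption proxy: for each user, the sum over the 12 food types of
#' the food's B12 content (mcg/100 g) times the number of the user's
#' recipe searches mentioning that food. The score is an intake proxy in
#' content units, not a calibrated absolute intake.
#'
#' @param profiles User profile table with one count column per food.
#' @param foods Food reference table.
#' @return The input tibble with a `b12_score` column appended.
#' @export
estimate_b12 <- function(profiles, foods = food_reference()) {
  miss <- setdiff(foods$food, names(profiles))
  if (length(miss) > 0) {
    stop("Missing food count column(s): ", paste(miss, collapse = ", "))
  }
  x <- as.matrix(profiles[foods$food])
  profiles$b12_score <- drop(x %*% foods$b12_mcg_100g)
  profiles
}

#' Contrast mean consumption scores between two groups
#'
#' Compares mean B12 consumption scores between users with and without a
#' flag (e.g. having asked about B12 deficiency). The headline relative
#' difference uses the flagged group's mean as the base:
#' `100 * (mean_unflagged - mean_flagged) / mean_flagged`; the
#' unflagged-base figure is also reported. Group difference is tested with
#' a two-sided Wilcoxon rank-sum test.
#'
#' @param scored Profile table carrying a `b12_score` column (see
#'   [estimate_b12()]) and the flag column.
#' @param flag Name of a logical column in `scored`.
#' @return A one-row tibble: `flag`, `n_flagged`, `n_unflagged`,
#'   `mean_flagged`, `mean_unflagged`, `relative_difference_pct`
#'   (flagged-base), `relative_difference_unflagged_base_pct`, `ranksum_p`.
#' @export
contrast_by_flag <- function(scored, flag) {
  stopifnot("b12_score" %in% names(scored), flag %in% names(scored))
  f <- scored[[flag]]
  stopifnot(is.logical(f))
  a <- scored$b12_score[f]
  b <- scored$b12_score[!f]
  if (length(a) == 0 || length(b) == 0) {
    stop("Both groups must be nonempty for flag `", flag, "`.")
  }
  tibble::tibble(
    flag = flag,
    n_flagged = length(a),
    n_unflagged = length(b),
    mean_flagged = mean(a),
    mean_unflagged = mean(b),
    relative_difference_pct = 100 * (mean(b) - mean(a)) / mean(a),
    relative_difference_unflagged_base_pct =
      100 * (mean(a) - mean(b)) / mean(b),
    ranksum_p = rank_sum_p(a, b)
  )
}

#' Supplement-query contingency from a 2x2 of counts
#'
#' Builds the deficiency-asker by supplement-asker contingency: `a` asked
#' both, `b` asked deficiency only, `c` asked supplements only, `d` asked
#' neither. Reports the supplement-asking proportion in each group, their
#' rate ratio, and the share of the population that never asked about
#' deficiency.
#'
#' @param a,b,c,d Counts of the 2x2 table.
#' @return A one-row tibble: the four counts,
#'   `p_supplement_given_deficiency`, `p_supplement_given_no_deficiency`,
#'   `rate_ratio` (Inf with `rate_ratio_infinite = TRUE` when no
#'   supplement askers exist among non-deficiency askers),
#'   `pct_no_deficiency`.
#' @export
supplement_contingency <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b > 0)
  p1 <- a / (a + b)
  p0 <- if (c + d > 0) c / (c + d) else NA_real_
  infinite <- !is.na(p0) && p0 == 0 && p1 > 0
  tibble::tibble(
    a = a, b = b, c = c, d = d,
    p_supplement_given_deficiency = p1,
    p_supplement_given_no_deficiency = p0,
    rate_ratio = if (infinite) Inf else p1 / p0,
    rate_ratio_infinite = infinite,
    pct_no_deficiency = 100 * (c + d) / (a + b + c + d)
  )
}

#' @rdname supplement_contingency
#' @param profiles User profile table with `asked_deficiency` and
#'   `asked_supplement` flags.
#' @return `supplement_contrast()` computes the 2x2 from profile flags and
#'   returns the same one-row tibble.
#' @export
supplement_contrast <- function(profiles) {
  stopifnot(
    all(c("asked_deficiency", "asked_supplement") %in% names(profiles))
  )
  def <- profiles$asked_deficiency
  sup <- profiles$asked_supplement
  if (!any(def)) stop("No deficiency askers in `profiles`.")
  supplement_contingency(
    a = sum(def & sup), b = sum(def & !sup),
    c = sum(!def & sup), d = sum(!def & !sup)
  )
}

#' Validate the consumption proxy against regional expenditure data
#'
#' Correlates cost-weighted regional recipe-query fractions (per food
#' category) with survey spending fractions over all region-by-category
#' cells, the package's analogue of validating recipe searches against
#' consumer-expenditure data.
#'
#' @param profiles User profile table (region + food counts).
#' @param foods Food reference table with `unit_cost`.
#' @param expenditure Tibble `region`, `category`, `fraction`.
#' @param mapping Food-to-category mapping.
#' @return A one-row tibble `pearson_r`, `p_value`, `n_cells`, `n_regions`.
#' @export
validate_regional <- function(profiles, foods, expenditure,
                              mapping = default_category_mapping()) {
  frac <- regional_cost_fractions(profiles, foods, mapping)
  joined <- dplyr::inner_join(
    frac, expenditure,
    by = c("region", "category"), suffix = c("_query", "_survey")
  )
  if (length(unique(joined$region)) < 2) {
    stop("Need at least 2 overlapping regions for the validation.")
  }
  ct <- stats::cor.test(
    joined$fraction_query, joined$fraction_survey, method = "pearson"
  )
  tibble::tibble(
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    n_cells = nrow(joined),
    n_regions = length(unique(joined$region))
  )
}
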