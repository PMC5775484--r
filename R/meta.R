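#' Spearman correlations of indication counts with term popularity
#'
#' Joins the per-term results with the drug-indication table and reports
#' Spearman correlations (two-sided p) of the number of indications, and of
#' the number of pain indications, with the number of askers.
#'
#' @param results Per-term result table from [fit_term_models()].
#' @param indications Tibble `term`, `n_indications`, `n_pain_indications`.
#' @return A one-row tibble `rho_ind_vs_n`, `p_ind_vs_n`, `rho_pain_vs_n`,
#'   `p_pain_vs_n`, `n_terms`.
#' @export
indication_correlations <- function(results, indications) {
  joined <- dplyr::inner_join(results, indications, by = "term")
  if (nrow(joined) < 3) {
    stop("Join of results and indications yields fewer than 3 terms.")
  }
  sp <- function(x, y) {
    suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE)
    )
  }
  a <- sp(joined$n_indications, joined$n_askers)
  b <- sp(joined$n_pain_indications, joined$n_askers)
  tibble::tibble(
    rho_ind_vs_n = unname(a$estimate), p_ind_vs_n = a$p.value,
    rho_pain_vs_n = unname(b$estimate), p_pain_vs_n = b$p.value,
    n_terms = nrow(joined)
  )
}

#' R2I-weighted rank-regression meta-model for CoB12
#'
#' Models CoB12 of drug terms as a function of term popularity, indication
#' breadth and pain-indication count. The response (CoB12) and the three
#' predictors are replaced by average ranks; predictor ranks are centered;
#' the design contains the three main effects, all pairwise interactions and
#' the three-way interaction; the fit is weighted least squares with weights
#' proportional to R2I (normalized to mean 1, so equal weights reduce to the
#' unweighted fit). If the rank design is collinear, interactions are
#' dropped in fixed order (three-way first, then pairwise) until full rank.
#'
#' Only terms present in the indication table (i.e. drugs) enter the model.
#'
#' @param results Per-term result table from [fit_term_models()].
#' @param indications Tibble `term`, `n_indications`, `n_pain_indications`.
#' @return An object of class `cob12_meta` with [tidy()] and [glance()]
#'   methods; `tidy()` reports slopes on the rank scale.
#' @export
fit_meta_model <- function(results, indications) {
  joined <- results |>
    dplyr::inner_join(indications, by = "term") |>
    dplyr::filter(!is.na(.data$cob12))
  if (nrow(joined) < 6) {
    stop("Need at least 6 drug terms after the join; got ", nrow(joined), ".")
  }
  dat <- tibble::tibble(
    term = joined$term,
    rank_cob12 = avg_rank(joined$cob12),
    rank_n_askers = center(avg_rank(joined$n_askers)),
    rank_n_indications = center(avg_rank(joined$n_indications)),
    rank_n_pain = center(avg_rank(joined$n_pain_indications)),
    weight = joined$r2i / mean(joined$r2i)
  )
  forms <- list(
    rank_cob12 ~ rank_n_askers * rank_n_indications * rank_n_pain,
    rank_cob12 ~ (rank_n_askers + rank_n_indications + rank_n_pain)^2,
    rank_cob12 ~ rank_n_askers + rank_n_indications + rank_n_pain +
      rank_n_askers:rank_n_indications + rank_n_askers:rank_n_pain,
    rank_cob12 ~ rank_n_askers + rank_n_indications + rank_n_pain +
      rank_n_askers:rank_n_indications,
    rank_cob12 ~ rank_n_askers + rank_n_indications + rank_n_pain
  )
  fit <- NULL
  for (f in forms) {
    fit <- stats::lm(f, data = dat, weights = dat$weight)
    if (!anyNA(stats::coef(fit))) break
    message("Collinear rank design; dropping the highest-order interaction.")
  }
  structure(
    list(
      fit = fit, data = dat, n_terms = nrow(dat),
      weights_used = "r2i", formula = stats::formula(fit)
    ),
    class = "cob12_meta"
  )
}

center <- function(x) x - mean(x)

#' @export
print.cob12_meta <- function(x, ...) {
  cat("<cob12_meta> R2I-weighted rank regression,", x$n_terms, "drug terms\n")
  cat("  weighted R2:", format(summary(x$fit)$r.squared, digits = 3), "\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy the meta-model fit
#'
#' @param x A `cob12_meta` object.
#' @param ... Unused.
#' @return A tibble `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`; estimates are rank-scale slopes.
#' @export
tidy.cob12_meta <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, 1], std.error = cf[, 2],
    statistic = cf[, 3], p.value = cf[, 4]
  )
}

#' Glance at the meta-model fit
#'
#' @param x A `cob12_meta` object.
#' @param ... Unused.
#' @return A one-row tibble `r.squared`, `adj.r.squared`, `sigma`,
#'   `p.value` (overall F), `nobs`, `weights_used`.
#' @export
glance.cob12_meta <- function(x, ...) {
  s <- summary(x$fit)
  fstat <- s$fstatistic
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    p.value = if (is.null(fstat)) NA_real_ else
      unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    nobs = x$n_terms,
    weights_used = x$weights_used
  )
}
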