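#' Plot per-term fit quality against CoB12
#'
#' Scatter of R2I (log scale) against CoB12, one point per term, colored by
#' set. Under the study hypothesis target terms sit below zero on the CoB12
#' axis while controls straddle it.
#'
#' @param results Per-term result table from [fit_term_models()].
#' @return A ggplot object.
#' @export
plot_term_association <- function(results) {
  ggplot2::ggplot(
    results,
    ggplot2::aes(x = .data$r2i, y = .data$cob12, colour = .data$set)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression(R[I]^2 ~ "(log scale)"),
      y = expression(CoB[12]),
      colour = "term set",
      title = "Per-term model fit vs coefficient-content correlation"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the regional expenditure validation
#'
#' Scatter of survey spending fractions against cost-weighted query
#' fractions, one point per region-by-category cell, with the identity
#' line.
#'
#' @param profiles User profile table.
#' @param foods Food reference table.
#' @param expenditure Expenditure table `region`, `category`, `fraction`.
#' @param mapping Food-to-category mapping.
#' @return A ggplot object.
#' @export
plot_regional_validation <- function(profiles, foods, expenditure,
                                     mapping = default_category_mapping()) {
  frac <- regional_cost_fractions(profiles, foods, mapping)
  joined <- dplyr::inner_join(
    frac, expenditure,
    by = c("region", "category"), suffix = c("_query", "_survey")
  )
  ggplot2::ggplot(
    joined,
    ggplot2::aes(
      x = .data$fraction_query, y = .data$fraction_survey,
      colour = .data$category
    )
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "cost-weighted query fraction", y = "survey spending fraction",
      title = "Recipe-search consumption proxy vs expenditure survey"
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot the meta-model fit
#'
#' Observed against fitted CoB12 ranks, point size proportional to the R2I
#' weight.
#'
#' @param object A `cob12_meta` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cob12_meta <- function(object, ...) {
  dat <- object$data
  dat$fitted <- stats::fitted(object$fit)
  ggplot2::ggplot(
    dat, ggplot2::aes(x = .data$fitted, y = .data$rank_cob12)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), alpha = 0.7) +
    ggplot2::labs(
      x = "fitted CoB12 rank", y = "observed CoB12 rank",
      size = "R2I weight",
      title = "Weighted rank-regression meta-model"
    ) +
    ggplot2::theme_minimal()
}
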