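#' Assemble the unified study report
#'
#' Collects the stage outputs into a single report object whose printed form
#' shows every headline number at the precision the field reports them
#' (percentages to one or two decimals, correlations to two). Missing
#' sections (e.g. no meta-model inputs) are marked absent rather than
#' failing. Reports from the same inputs are byte-identical.
#'
#' @param contrasts Tibble of group contrasts from [contrast_by_flag()]
#'   (one row per flag).
#' @param contingency One-row tibble from [supplement_contrast()].
#' @param regional One-row tibble from [validate_regional()], or NULL.
#' @param top_terms Top-k term table from [rank_terms()].
#' @param set_contrast One-row tibble from [contrast_sets()].
#' @param correlations One-row tibble from [popularity_correlations()].
#' @param tomato One-row tibble from [tomato_check()], or NULL.
#' @param indication_cors One-row tibble from [indication_correlations()],
#'   or NULL.
#' @param meta A `cob12_meta` object, or NULL.
#' @param config The [sim_config()] used, or NULL for real data.
#' @return An object of class `cob12_report`; `format()` yields the report
#'   lines, `print()` writes them.
#' @export
build_report <- function(contrasts = NULL, contingency = NULL,
                         regional = NULL, top_terms = NULL,
                         set_contrast = NULL, correlations = NULL,
                         tomato = NULL, indication_cors = NULL,
                         meta = NULL, config = NULL) {
  structure(
    list(
      contrasts = contrasts, contingency = contingency, regional = regional,
      top_terms = top_terms, set_contrast = set_contrast,
      correlations = correlations, tomato = tomato,
      indication_cors = indication_cors, meta = meta, config = config
    ),
    class = "cob12_report"
  )
}

#' @export
format.cob12_report <- function(x, ...) {
  num <- function(v, d = 2) formatC(v, format = "f", digits = d)
  lines <- c("== B12 search-pattern study report ==")
  if (!is.null(x$config)) {
    lines <- c(lines, sprintf(
      "config: %d users, %d recipes, %d regions, seed %d",
      x$config$n_users, x$config$n_recipes, x$config$n_regions, x$config$seed
    ))
  }
  lines <- c(lines, "", "-- consumption contrasts --")
  if (is.null(x$contrasts)) {
    lines <- c(lines, "absent")
  } else {
    for (i in seq_len(nrow(x$contrasts))) {
      r <- x$contrasts[i, ]
      lines <- c(lines, sprintf(
        "%s: mean %s (n=%d) vs %s (n=%d); rel diff %s%% (flagged base); ranksum p=%s",
        r$flag, num(r$mean_flagged, 3), r$n_flagged,
        num(r$mean_unflagged, 3), r$n_unflagged,
        num(r$relative_difference_pct, 1), format(r$ranksum_p, digits = 2)
      ))
    }
  }
  lines <- c(lines, "", "-- supplement contingency --")
  if (is.null(x$contingency)) {
    lines <- c(lines, "absent")
  } else {
    ct <- x$contingency
    lines <- c(lines, sprintf(
      "deficiency askers asking supplements: %s%% (%d/%d); others: %s%% (%d/%d); rate ratio %s; %s%% never asked",
      num(100 * ct$p_supplement_given_deficiency, 2), ct$a, ct$a + ct$b,
      num(100 * ct$p_supplement_given_no_deficiency, 2), ct$c, ct$c + ct$d,
      num(ct$rate_ratio, 0), num(ct$pct_no_deficiency, 2)
    ))
  }
  lines <- c(lines, "", "-- regional validation --")
  lines <- c(lines, if (is.null(x$regional)) "absent" else sprintf(
    "Pearson r=%s (p=%s, N=%d cells, %d regions)",
    num(x$regional$pearson_r, 2), format(x$regional$p_value, digits = 2),
    x$regional$n_cells, x$regional$n_regions
  ))
  lines <- c(lines, "", "-- top terms by R2I --")
  if (is.null(x$top_terms)) {
    lines <- c(lines, "absent")
  } else {
    for (i in seq_len(nrow(x$top_terms))) {
      r <- x$top_terms[i, ]
      lines <- c(lines, sprintf(
        "%-24s %s  R2I=%s  CoB12=%s  n=%d",
        r$term, r$set, format(r$r2i, digits = 3), num(r$cob12, 3), r$n_askers
      ))
    }
  }
  lines <- c(lines, "", "-- target vs control sets --")
  lines <- c(lines, if (is.null(x$set_contrast)) "absent" else sprintf(
    "median R2I ratio (top %d) = %s (ranksum p=%s); mean CoB12 target %s vs control %s (ranksum p=%s)",
    x$set_contrast$k_used, num(x$set_contrast$median_ratio, 1),
    format(x$set_contrast$ranksum_p_r2i, digits = 2),
    num(x$set_contrast$mean_cob12_target, 2),
    num(x$set_contrast$mean_cob12_control, 2),
    format(x$set_contrast$ranksum_p_cob12, digits = 2)
  ))
  lines <- c(lines, "", "-- correlations --")
  lines <- c(lines, if (is.null(x$correlations)) "absent" else sprintf(
    "Spearman R2I~n(target) rho=%s (p=%s); R2I~CoB12 target rho=%s (p=%s); control rho=%s (p=%s)",
    num(x$correlations$rho_r2i_vs_n, 2),
    format(x$correlations$p_r2i_vs_n, digits = 2),
    num(x$correlations$rho_r2i_vs_cob12_target, 2),
    format(x$correlations$p_r2i_vs_cob12_target, digits = 2),
    num(x$correlations$rho_r2i_vs_cob12_control, 2),
    format(x$correlations$p_r2i_vs_cob12_control, digits = 2)
  ))
  lines <- c(lines, if (is.null(x$tomato)) NULL else sprintf(
    "tomato check: mean |beta| foods/tomato ratio = %s",
    num(x$tomato$ratio, 1)
  ))
  lines <- c(lines, "", "-- drug indications & meta-model --")
  if (is.null(x$indication_cors)) {
    lines <- c(lines, "indication correlations: absent")
  } else {
    lines <- c(lines, sprintf(
      "Spearman indications~n rho=%s (p=%s); pain indications~n rho=%s (p=%s); N=%d",
      num(x$indication_cors$rho_ind_vs_n, 2),
      format(x$indication_cors$p_ind_vs_n, digits = 2),
      num(x$indication_cors$rho_pain_vs_n, 2),
      format(x$indication_cors$p_pain_vs_n, digits = 2),
      x$indication_cors$n_terms
    ))
  }
  if (is.null(x$meta)) {
    lines <- c(lines, "meta-model: absent")
  } else {
    g <- glance(x$meta)
    td <- tidy(x$meta)
    lines <- c(lines, sprintf(
      "rank regression (weights=R2I): R2=%s (p=%s, N=%d)",
      num(g$r.squared, 2), format(g$p.value, digits = 2), g$nobs
    ))
    for (i in seq_len(nrow(td))) {
      lines <- c(lines, sprintf(
        "  %-40s slope=%s p=%s",
        td$term[i], num(td$estimate[i], 2), format(td$p.value[i], digits = 2)
      ))
    }
  }
  lines
}

#' @export
print.cob12_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
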