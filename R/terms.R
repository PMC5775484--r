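#' Fit the individual-level linear probability model for one term
#'
#' Ordinary least squares of the 0/1 ask indicator on the 12 raw food
#' search counts plus an intercept. The goodness of fit R2I is the
#' coefficient of determination. A rank-deficient design is solved by the
#' minimum-norm least-squares solution with a warning.
#'
#' @param food_counts Numeric user-by-food matrix (or data frame) of raw
#'   counts, columns in canonical food order.
#' @param ask_flags Logical (or 0/1) vector: whether each user asked about
#'   the term.
#' @return A list with `coefficients` (named, length 12), `intercept`,
#'   `r2i` and `n_askers`.
#' @export
fit_term_model <- function(food_counts, ask_flags) {
  x <- as.matrix(food_counts)
  y <- as.numeric(ask_flags)
  stopifnot(nrow(x) == length(y))
  if (nrow(x) < ncol(x) + 1) {
    stop("Need at least ", ncol(x) + 1, " users to fit the model.")
  }
  if (stats::var(y) == 0) {
    stop("`ask_flags` is constant; R2 is undefined.")
  }
  design <- cbind(`(Intercept)` = 1, x)
  fit <- stats::.lm.fit(design, y)
  if (fit$rank < ncol(design)) {
    warning("Rank-deficient design; using the minimum-norm solution.")
    sv <- svd(design)
    pos <- sv$d > max(sv$d) * 1e-12
    coefs <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    coefs <- drop(coefs)
    names(coefs) <- colnames(design)
    resid <- y - drop(design %*% coefs)
  } else {
    coefs <- fit$coefficients
    coefs[fit$pivot] <- fit$coefficients  # undo any column pivoting
    names(coefs) <- colnames(design)
    resid <- fit$residuals
  }
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(
    coefficients = coefs[-1],
    intercept = unname(coefs[1]),
    r2i = r2,
    n_askers = sum(y > 0)
  )
}

#' CoB12: correlation between model coefficients and B12 contents
#'
#' The summary statistic of the analysis: the correlation between a term
#' model's per-food coefficients and the foods' B12 contents, in the
#' canonical food order. Negative CoB12 means users searching for B12-rich
#' foods ask about the term less. Pearson by default; Spearman available.
#'
#' @param coefficients Numeric coefficient vector aligned with `foods` (if
#'   named, it is re-aligned by name).
#' @param foods Food reference table.
#' @param method "pearson" (default) or "spearman".
#' @return A one-row tibble `cob12`, `p_value`, `method`. A zero-variance
#'   coefficient vector gives NA with a warning.
#' @export
compute_cob12 <- function(coefficients, foods = food_reference(),
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.null(names(coefficients))) {
    miss <- setdiff(foods$food, names(coefficients))
    if (length(miss) > 0) {
      stop("Coefficients missing food(s): ", paste(miss, collapse = ", "))
    }
    coefficients <- coefficients[foods$food]
  }
  stopifnot(length(coefficients) == nrow(foods))
  if (stats::sd(coefficients) == 0) {
    warning("Zero-variance coefficient vector; CoB12 undefined.")
    return(tibble::tibble(
      cob12 = NA_real_, p_value = NA_real_, method = method
    ))
  }
  ct <- suppressWarnings(stats::cor.test(
    as.numeric(coefficients), foods$b12_mcg_100g,
    method = method, exact = FALSE
  ))
  tibble::tibble(
    cob12 = unname(ct$estimate), p_value = ct$p.value, method = method
  )
}

#' Fit per-term models and compute R2I and CoB12 for a set of terms
#'
#' Runs [fit_term_model()] for every retained term and assembles the
#' per-term result table (the analogue of the study's per-term regression
#' table): coefficients over the 12 foods, intercept, R2I, asker count and
#' CoB12.
#'
#' @param profiles User profile table from [aggregate_users()].
#' @param terms Term table with `term` and `set` columns (typically the
#'   output of [filter_terms()]); defaults to all lexicon terms present.
#' @param foods Food reference table.
#' @param cob12_method Correlation type for CoB12.
#' @return A tibble with one row per term: `term`, `set`, `n_askers`,
#'   `r2i`, `cob12`, `cob12_p`, `intercept` and one `beta_<food>` column
#'   per food.
#' @export
fit_term_models <- function(profiles, terms, foods = food_reference(),
                            cob12_method = "pearson") {
  stopifnot(all(c("term", "set") %in% names(terms)))
  x <- as.matrix(profiles[foods$food])
  rows <- purrr::pmap(
    list(terms$term, terms$set),
    function(trm, set) {
      col <- term_column(trm)
      if (!col %in% names(profiles)) {
        stop("Profiles lack term flag column for `", trm, "`.")
      }
      fit <- fit_term_model(x, profiles[[col]])
      cb <- compute_cob12(fit$coefficients, foods, method = cob12_method)
      out <- tibble::tibble(
        term = trm, set = set, n_askers = fit$n_askers,
        r2i = fit$r2i, cob12 = cb$cob12, cob12_p = cb$p_value,
        intercept = fit$intercept
      )
      betas <- tibble::as_tibble(as.list(fit$coefficients)) |>
        rlang::set_names(paste0("beta_", foods$food))
      dplyr::bind_cols(out, betas)
    }
  )
  dplyr::bind_rows(rows)
}

#' Rank terms by goodness of fit
#'
#' Sorts the per-term results by R2I descending (ties: larger asker count,
#' then label) and returns the top k — the analogue of the study's table of
#' the best-fitting terms.
#'
#' @param results Per-term result table from [fit_term_models()].
#' @param k Number of terms to keep.
#' @return The top-k rows of `results`, sorted.
#' @export
rank_terms <- function(results, k = 10) {
  stopifnot(nrow(results) > 0)
  results |>
    dplyr::arrange(
      dplyr::desc(.data$r2i), dplyr::desc(.data$n_askers), .data$term
    ) |>
    dplyr::slice_head(n = k)
}

#' Contrast target and control term sets
#'
#' Compares the two term sets: the ratio of median R2I over the top-k terms
#' of each set (with a rank-sum test on the two top-k R2I samples), and the
#' mean CoB12 of each full set (with a rank-sum test on the per-term CoB12
#' values).
#'
#' @param results Per-term result table with both sets.
#' @param k Top-k convention for the R2I comparison; lowered to the smaller
#'   set size with a message if needed.
#' @return A one-row tibble: `k_used`, `median_r2i_target`,
#'   `median_r2i_control`, `median_ratio`, `ranksum_p_r2i`,
#'   `mean_cob12_target`, `mean_cob12_control`, `ranksum_p_cob12`.
#' @export
contrast_sets <- function(results, k = 10) {
  tgt <- dplyr::filter(results, .data$set == "target")
  ctl <- dplyr::filter(results, .data$set == "control")
  if (nrow(tgt) == 0 || nrow(ctl) == 0) {
    stop("Both term sets must be nonempty.")
  }
  k_used <- min(k, nrow(tgt), nrow(ctl))
  if (k_used < k) {
    message("Lowering k from ", k, " to ", k_used, " (smaller set size).")
  }
  top_t <- rank_terms(tgt, k_used)$r2i
  top_c <- rank_terms(ctl, k_used)$r2i
  tibble::tibble(
    k_used = k_used,
    median_r2i_target = stats::median(top_t),
    median_r2i_control = stats::median(top_c),
    median_ratio = stats::median(top_t) / stats::median(top_c),
    ranksum_p_r2i = rank_sum_p(top_t, top_c),
    mean_cob12_target = mean(tgt$cob12, na.rm = TRUE),
    mean_cob12_control = mean(ctl$cob12, na.rm = TRUE),
    ranksum_p_cob12 = rank_sum_p(
      tgt$cob12[!is.na(tgt$cob12)], ctl$cob12[!is.na(ctl$cob12)]
    )
  )
}

#' Spearman correlations of R2I with popularity and CoB12
#'
#' Reports the Spearman rank correlation (average ranks on ties, two-sided
#' p) of R2I with the number of askers over the target set, and of R2I with
#' CoB12 separately within each set.
#'
#' @param results Per-term result table.
#' @return A one-row tibble with `rho_r2i_vs_n`, `rho_r2i_vs_cob12_target`,
#'   `rho_r2i_vs_cob12_control` and their p-values.
#' @export
popularity_correlations <- function(results) {
  spear <- function(x, y) {
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 3) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(x[keep], y[keep], method = "spearman", exact = FALSE)
    )
    c(unname(ct$estimate), ct$p.value)
  }
  tgt <- dplyr::filter(results, .data$set == "target")
  ctl <- dplyr::filter(results, .data$set == "control")
  a <- spear(tgt$r2i, tgt$n_askers)
  b <- spear(tgt$r2i, tgt$cob12)
  d <- spear(ctl$r2i, ctl$cob12)
  tibble::tibble(
    rho_r2i_vs_n = a[1], p_r2i_vs_n = a[2],
    rho_r2i_vs_cob12_target = b[1], p_r2i_vs_cob12_target = b[2],
    rho_r2i_vs_cob12_control = d[1], p_r2i_vs_cob12_control = d[2]
  )
}

#' Tomato negative-control check
#'
#' Tomatoes carry negligible B12, so under the study hypothesis their
#' regression coefficients should be small relative to the B12-bearing
#' foods. Returns the ratio of the mean (over terms) of the mean absolute
#' coefficient across the 11 B12-bearing foods to the mean absolute tomato
#' coefficient.
#'
#' @param results Per-term result table with `beta_` columns including
#'   `beta_tomato`.
#' @param foods Food reference table.
#' @return A one-row tibble `mean_abs_beta_foods`, `mean_abs_beta_tomato`,
#'   `ratio`, `ratio_infinite`.
#' @export
tomato_check <- function(results, foods = food_reference()) {
  if (!"beta_tomato" %in% names(results)) {
    stop("Tomato predictor absent: no `beta_tomato` column in `results`.")
  }
  other <- paste0("beta_", setdiff(foods$food, "tomato"))
  miss <- setdiff(other, names(results))
  if (length(miss) > 0) {
    stop("Missing coefficient column(s): ", paste(miss, collapse = ", "))
  }
  m_other <- mean(rowMeans(abs(as.matrix(results[other]))))
  m_tomato <- mean(abs(results$beta_tomato))
  infinite <- m_tomato == 0 && m_other > 0
  tibble::tibble(
    mean_abs_beta_foods = m_other,
    mean_abs_beta_tomato = m_tomato,
    ratio = if (infinite) Inf else m_other / m_tomato,
    ratio_infinite = infinite
  )
}
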