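#' Aggregate a query-event stream into per-user profiles
#'
#' Turns raw query events into the per-user feature table the analyses
#' consume. Each event is recipe-matched, B12-classified and term-matched;
#' per user, `food_counts[i]` is the number of events whose matched recipe
#' contains food i (an event matching a k-ingredient recipe increments all k
#' food counters), term flags record whether any event matched the term,
#' B12 flags record whether any event was classified accordingly, and the
#' region is the modal region over the user's events (smallest code on
#' ties). Users with no recipe matches are retained with a zero count
#' vector. Aggregation is order-independent.
#'
#' @param events Tibble with columns `user_id`, `text`, `region`.
#' @param recipes Recipe corpus.
#' @param lexicon Term lexicon.
#' @param foods Food reference table.
#' @return A tibble with one row per user: `user_id`, `region`, one count
#'   column per food (canonical order), `asked_b12`, `asked_deficiency`,
#'   `asked_supplement`, `asked_level`, and one `ask_<term>` logical column
#'   per lexicon term.
#' @export
aggregate_users <- function(events, recipes, lexicon,
                            foods = food_reference()) {
  stopifnot(all(c("user_id", "text", "region") %in% names(events)))
  bad <- is.na(events$user_id) | events$user_id == ""
  if (any(bad)) {
    message("Skipping ", sum(bad), " event(s) with empty user_id.")
    events <- events[!bad, , drop = FALSE]
  }
  if (nrow(events) == 0) stop("No events to aggregate.")
  food_names <- foods$food

  norm <- normalize_text(events$text)
  uniq <- unique(norm)
  u_of <- match(norm, uniq)

  rec <- match_recipes(uniq, recipes)
  b12 <- classify_b12_query(uniq)
  tm <- match_terms_matrix(uniq, lexicon)

  users <- sort(unique(events$user_id))
  uid <- match(events$user_id, users)
  n_u <- length(users)

  # food counts: event -> matched recipe -> its ingredients
  ing_long <- recipe_ingredients_long(recipes)
  ing_by_recipe <- split(
    match(ing_long$food, food_names), ing_long$recipe_id
  )
  ev_rec <- rec[u_of]
  has_rec <- !is.na(ev_rec)
  counts <- matrix(0L, n_u, 12, dimnames = list(NULL, food_names))
  if (any(has_rec)) {
    ing_sets <- ing_by_recipe[ev_rec[has_rec]]
    long_u <- rep(uid[has_rec], lengths(ing_sets))
    long_f <- unlist(ing_sets, use.names = FALSE)
    tal <- table(factor(long_u, seq_len(n_u)), factor(long_f, seq_len(12)))
    counts[] <- as.integer(tal)
  }

  flag_by_user <- function(v) {
    as.logical(rowsum(as.integer(v[u_of]), uid, reorder = TRUE) > 0)
  }
  prof <- dplyr::bind_cols(
    tibble::tibble(
      user_id = users,
      region = modal_region(uid, events$region, n_u)
    ),
    tibble::as_tibble(as.data.frame(counts)),
    tibble::tibble(
      asked_b12 = flag_by_user(b12$is_b12),
      asked_deficiency = flag_by_user(b12$is_deficiency),
      asked_supplement = flag_by_user(b12$is_supplement),
      asked_level = flag_by_user(b12$is_level)
    )
  )
  for (j in seq_len(ncol(tm))) {
    prof[[term_column(colnames(tm)[j])]] <- flag_by_user(tm[, j])
  }
  prof
}

# modal region per user id index; smallest region code wins ties
modal_region <- function(uid, region, n_u) {
  tab <- table(factor(uid, seq_len(n_u)), region)
  regs <- as.integer(colnames(tab))
  ord <- order(regs)
  tab <- tab[, ord, drop = FALSE]
  regs[ord][max.col(tab, ties.method = "first")]
}

#' Filter terms by minimum number of askers
#'
#' Retains the lexicon terms asked about by at least `min_askers` users and
#' reports asker counts, emulating the study's inclusion rule for analysis
#' terms.
#'
#' @param profiles User profile table from [aggregate_users()].
#' @param lexicon Term lexicon.
#' @param min_askers Minimum number of distinct askers (inclusive).
#' @return A tibble `term`, `set`, `is_drug`, `n_askers`, sorted by
#'   `n_askers` descending, containing only retained terms.
#' @export
filter_terms <- function(profiles, lexicon, min_askers = 1000) {
  if (min_askers < 1) stop("`min_askers` must be at least 1.")
  lex <- lexicon
  lex$term <- normalize_text(lex$term)
  if (!"is_drug" %in% names(lex)) lex$is_drug <- TRUE
  cols <- term_column(lex$term)
  miss <- setdiff(cols, names(profiles))
  if (length(miss) > 0) {
    stop("Profiles lack term flag column(s): ", paste(miss, collapse = ", "))
  }
  lex$n_askers <- unname(vapply(
    cols, function(cl) sum(profiles[[cl]]), integer(1)
  ))
  lex |>
    dplyr::filter(.data$n_askers >= min_askers) |>
    dplyr::arrange(dplyr::desc(.data$n_askers), .data$term) |>
    dplyr::select("term", "set", "is_drug", "n_askers")
}
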