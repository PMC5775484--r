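# unrelated filler queries; share no token with foods, terms or B12 strings
noise_phrases <- c(
  "weather tomorrow", "news today", "movie showtimes", "football scores",
  "flight status", "bank login", "directions home", "lottery numbers",
  "daily horoscope", "netflix shows", "car insurance quotes", "cheap flights",
  "election results", "stock prices", "translate hello", "world map",
  "phone deals", "music videos", "game scores", "job listings"
)

term_query_suffixes <- c(
  "dosage", "side effects", "uses", "reviews", "dose", "withdrawal",
  "what is", "half life"
)

#' Generate a synthetic query-event log with ground truth
#'
#' Simulates one month of searches for a population of users. Each user
#' draws a diet preference over the 12 foods from a Dirichlet distribution;
#' recipe queries are emitted at a Poisson rate, each for a recipe drawn by
#' preference over its ingredients; the user's latent B12 intake is the
#' expected value of the downstream consumption estimator given their
#' preference (content-weighted expected food mentions). Whether a user asks
#' about each medical term follows a logistic model whose log-odds shift
#' with latent intake by the configured per-term effect. Users aware of B12
#' deficiency (rate `awareness_rate`) have their preference tilted toward
#' low-B12 foods and emit a B12-deficiency query; supplement queries are
#' emitted with the two configured conditional probabilities. Every user
#' appears in the log at least once (the study population is people who
#' searched at all).
#'
#' @param config A [sim_config()] object.
#' @param recipes Recipe corpus from [simulate_recipes()].
#' @return A list with elements:
#'   * `events`: tibble `event_id`, `user_id`, `text`, `region` — the only
#'     table analysis stages may consume;
#'   * `truth`: ground truth, a list of `users` (per-user region, awareness
#'     flag, latent intake, preference vector), `terms` (per-term true effect
#'     and baseline), `event_recipes` (true recipe behind each recipe query)
#'     and `food_counts` (per-user true food-mention tallies).
#' @export
simulate_search_log <- function(config, recipes) {
  stopifnot(inherits(config, "cob12_config"))
  if (!is.data.frame(recipes) || nrow(recipes) == 0) {
    stop("`recipes` must be a nonempty recipe corpus.")
  }
  foods <- food_reference()
  food_names <- foods$food
  contents <- foods$b12_mcg_100g
  n <- config$n_users
  lex <- config$lexicon

  ing_long <- recipe_ingredients_long(recipes)
  recipes_by_food <- split(ing_long$recipe_id, factor(ing_long$food, food_names))
  if (any(lengths(recipes_by_food) == 0)) {
    stop(
      "Corpus lacks recipes for: ",
      paste(food_names[lengths(recipes_by_food) == 0], collapse = ", ")
    )
  }
  # M[f, i]: P(recipe drawn for food f contains food i)
  ing_sets <- lapply(recipes$ingredients, function(x) match(x, food_names))
  M <- matrix(0, 12, 12, dimnames = list(food_names, food_names))
  for (r in seq_along(ing_sets)) {
    f_idx <- ing_sets[[r]]
    M[f_idx, f_idx] <- M[f_idx, f_idx] + 1
  }
  M <- M / pmax(lengths(recipes_by_food), 1)

  with_seed_offset(config$seed, 202L, {
    user_id <- sprintf("u%06d", seq_len(n))
    region <- sample.int(config$n_regions, n, replace = TRUE) - 1L
    aware <- stats::runif(n) < config$awareness_rate

    alpha <- config$diet_concentration * 12 * config$ingredient_weights
    pref <- rdirichlet_mat(n, alpha)
    tilt <- exp(config$awareness_intake_shift * contents)
    if (any(aware)) {
      pa <- pref[aware, , drop = FALSE] * rep(tilt, each = sum(aware))
      pref[aware, ] <- pa / rowSums(pa)
    }
    colnames(pref) <- food_names

    lambda <- config$mean_food_searches
    exp_counts <- lambda * (pref %*% M)
    intake <- drop(exp_counts %*% contents)
    intake_centered <- intake - mean(intake)

    # recipe queries
    k_u <- stats::rpois(n, lambda)
    uidx <- rep(seq_len(n), k_u)
    n_ev <- length(uidx)
    food_idx <- integer(0)
    rec_ids <- character(0)
    if (n_ev > 0) {
      cdf <- t(apply(pref, 1, cumsum))
      r <- stats::runif(n_ev)
      food_idx <- rowSums(r > cdf[uidx, , drop = FALSE]) + 1L
      rec_ids <- character(n_ev)
      for (f in seq_len(12)) {
        sel <- food_idx == f
        if (any(sel)) {
          pool <- recipes_by_food[[f]]
          rec_ids[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
        }
      }
    }
    title_of <- stats::setNames(recipes$title, recipes$recipe_id)
    recipe_events <- tibble::tibble(
      user = uidx,
      text = paste(unname(title_of[rec_ids]), "recipe"),
      recipe_id = rec_ids
    )

    # term queries
    ask <- matrix(FALSE, n, nrow(lex), dimnames = list(NULL, lex$term))
    term_event_list <- vector("list", nrow(lex))
    for (j in seq_len(nrow(lex))) {
      trm <- lex$term[j]
      p <- stats::plogis(
        stats::qlogis(config$baseline_term_rates[[trm]]) +
          config$term_effects[[trm]] * intake_centered
      )
      ask[, j] <- stats::runif(n) < p
      who <- which(ask[, j])
      if (length(who) > 0) {
        sfx <- sample(term_query_suffixes, length(who), replace = TRUE)
        term_event_list[[j]] <- tibble::tibble(
          user = who,
          text = ifelse(sfx == "what is", paste(sfx, trm), paste(trm, sfx))
        )
      }
    }
    term_events <- dplyr::bind_rows(term_event_list)

    # B12 queries: awareness drives deficiency queries; supplements per the
    # two conditionals
    def_events <- tibble::tibble(
      user = which(aware),
      text = "vitamin b12 deficiency"
    )
    p_supp <- ifelse(
      aware,
      config$supplement_given_awareness,
      config$supplement_given_no_awareness
    )
    supp <- stats::runif(n) < p_supp
    supp_events <- tibble::tibble(
      user = which(supp),
      text = "b12 supplements"
    )

    # filler noise; then guarantee every user appears in the log
    k_noise <- stats::rpois(n, config$noise_queries_per_user)
    seen <- unique(c(recipe_events$user, term_events$user,
                     def_events$user, supp_events$user))
    unseen <- setdiff(which(k_noise == 0L), seen)
    k_noise[unseen] <- 1L
    nidx <- rep(seq_len(n), k_noise)
    noise_events <- tibble::tibble(
      user = nidx,
      text = sample(noise_phrases, length(nidx), replace = TRUE)
    )

    events <- dplyr::bind_rows(
      recipe_events[c("user", "text")], term_events, def_events,
      supp_events, noise_events
    )
    events <- tibble::tibble(
      event_id = seq_len(nrow(events)),
      user_id = user_id[events$user],
      text = events$text,
      region = region[events$user]
    )

    event_recipes <- tibble::tibble(
      event_id = seq_len(nrow(recipe_events)),
      recipe_id = recipe_events$recipe_id
    )

    # true per-user food-mention tallies (what aggregation should recover)
    food_counts <- matrix(
      0L, n, 12, dimnames = list(NULL, food_names)
    )
    if (n_ev > 0) {
      rec_rows <- match(rec_ids, recipes$recipe_id)
      long_u <- rep(uidx, lengths(ing_sets[rec_rows]))
      long_f <- unlist(ing_sets[rec_rows], use.names = FALSE)
      tally <- table(factor(long_u, seq_len(n)), factor(long_f, seq_len(12)))
      food_counts[] <- as.integer(tally)
    }
    truth_users <- dplyr::bind_cols(
      tibble::tibble(
        user_id = user_id, region = region, aware = aware,
        latent_intake = intake
      ),
      tibble::as_tibble(as.data.frame(pref)) |>
        rlang::set_names(paste0("pref_", food_names))
    )
    truth <- list(
      users = truth_users,
      terms = tibble::tibble(
        term = lex$term, set = lex$set, is_drug = lex$is_drug,
        effect = unname(config$term_effects[lex$term]),
        baseline = unname(config$baseline_term_rates[lex$term])
      ),
      event_recipes = event_recipes,
      food_counts = dplyr::bind_cols(
        tibble::tibble(user_id = user_id),
        tibble::as_tibble(as.data.frame(food_counts))
      )
    )
    list(events = events, truth = truth)
  })
}
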