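#' Match query texts to recipes
#'
#' Transparent token matcher standing in for a recipe-intent classifier. A
#' query matches a recipe when all of the recipe's title tokens occur in the
#' query (order-free, token-boundary), or — failing that — when the query
#' contains the token "recipe" plus at least one ingredient name. Ties are
#' broken by most title tokens matched, then lexicographically smallest
#' `recipe_id`.
#'
#' @param texts Character vector of raw query texts.
#' @param recipes Recipe corpus (see [simulate_recipes()]).
#' @return Character vector of matched `recipe_id`s (NA for non-matches),
#'   aligned with `texts`.
#' @export
match_recipes <- function(texts, recipes) {
  stopifnot(is.data.frame(recipes), nrow(recipes) > 0)
  idx <- recipe_token_index(recipes)
  norm <- normalize_text(texts)
  uniq <- unique(norm)
  utoks <- tokenize(uniq)
  utoks <- lapply(utoks, unique)

  # fast path: query tokens minus "recipe" exactly equal a recipe's token set
  recipe_keys <- vapply(
    tokenize(recipes$title),
    function(t) paste(sort(unique(t)), collapse = " "),
    character(1)
  )
  key_best <- tibble::tibble(key = recipe_keys, recipe_id = recipes$recipe_id) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(recipe_id = min(.data$recipe_id), .groups = "drop")
  qkeys <- vapply(
    utoks,
    function(t) paste(sort(setdiff(t, "recipe")), collapse = " "),
    character(1)
  )
  hit <- key_best$recipe_id[match(qkeys, key_best$key)]

  # general path for the rest: inverted index + containment count
  todo <- which(is.na(hit) & lengths(utoks) > 0)
  if (length(todo) > 0) {
    postings <- split(idx$long$recipe_id, idx$long$token)
    ntok <- stats::setNames(idx$n_tokens$n_tokens, idx$n_tokens$recipe_id)
    ing_long <- recipe_ingredients_long(recipes)
    by_ing <- split(ing_long$recipe_id, ing_long$food)
    for (q in todo) {
      toks <- utoks[[q]]
      posts <- postings[intersect(toks, names(postings))]
      cand <- unlist(posts, use.names = FALSE)
      if (length(cand) > 0) {
        matched <- table(cand)
        full <- matched[matched == ntok[names(matched)]]
        if (length(full) > 0) {
          best <- as.integer(full) == max(as.integer(full))
          hit[q] <- min(names(full)[best])
          next
        }
      }
      # fallback: "recipe" + >=1 ingredient name
      if ("recipe" %in% toks) {
        ing_hit <- intersect(toks, names(by_ing))
        if (length(ing_hit) > 0) {
          cand2 <- unique(unlist(by_ing[ing_hit], use.names = FALSE))
          m2 <- if (length(cand) > 0) matched[cand2] else NULL
          score <- rep(0L, length(cand2))
          if (!is.null(m2)) score[!is.na(m2)] <- as.integer(m2[!is.na(m2)])
          best <- score == max(score)
          hit[q] <- min(cand2[best])
        }
      }
    }
  }
  unname(hit[match(norm, uniq)])
}

#' @rdname match_recipes
#' @param text A single query text.
#' @return `match_recipe()` returns a single `recipe_id` or `NA_character_`.
#' @export
match_recipe <- function(text, recipes) {
  stopifnot(length(text) == 1)
  match_recipes(text, recipes)
}

#' Classify B12-related queries
#'
#' A query is a B12 query when it contains the token "b12" (also written
#' "b-12" or "b 12"). B12 queries are sub-classified by keywords:
#' deficiency (deficiency/deficient/low), supplements
#' (supplement(s)/pill(s)/injection(s)/shot(s)) and serum level
#' (level(s)/test/serum). Sub-flags imply the B12 flag.
#'
#' @param texts Character vector of raw query texts.
#' @return A tibble with logical columns `is_b12`, `is_deficiency`,
#'   `is_supplement`, `is_level`, one row per input text.
#' @export
classify_b12_query <- function(texts) {
  norm <- paste0(" ", normalize_text(texts), " ")
  has_any <- function(words) {
    Reduce(`|`, lapply(words, function(w) {
      stringr::str_detect(norm, stringr::fixed(paste0(" ", w, " ")))
    }))
  }
  is_b12 <- has_any("b12")
  tibble::tibble(
    is_b12 = is_b12,
    is_deficiency = is_b12 & has_any(c("deficiency", "deficient", "low")),
    is_supplement = is_b12 & has_any(c(
      "supplement", "supplements", "pill", "pills",
      "injection", "injections", "shot", "shots"
    )),
    is_level = is_b12 & has_any(c("level", "levels", "test", "serum"))
  )
}

#' Match medical terms in query texts
#'
#' A term matches when its full normalized string occurs contiguously at
#' token boundaries in the query; multi-word terms must appear as a
#' contiguous token run. A query may match several terms.
#'
#' @param texts Character vector of raw query texts.
#' @param lexicon Term lexicon with a `term` column.
#' @return A logical matrix, one row per text and one column per lexicon
#'   term.
#' @export
match_terms_matrix <- function(texts, lexicon) {
  terms <- normalize_text(lexicon$term)
  padded <- paste0(" ", normalize_text(texts), " ")
  out <- vapply(
    terms,
    function(trm) {
      stringr::str_detect(padded, stringr::fixed(paste0(" ", trm, " ")))
    },
    logical(length(texts))
  )
  out <- matrix(out, nrow = length(texts), dimnames = list(NULL, terms))
  out
}

#' @rdname match_terms_matrix
#' @param text A single query text.
#' @return `match_terms()` returns the character vector of matching terms.
#' @export
match_terms <- function(text, lexicon) {
  stopifnot(length(text) == 1)
  m <- match_terms_matrix(text, lexicon)
  colnames(m)[m[1, ]]
}
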