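# filler vocabulary for recipe titles; never contains "recipe", a food name
# or any lexicon term
recipe_fillers <- c(
  "soup", "stew", "salad", "pie", "grilled", "roast", "curry", "casserole",
  "baked", "spicy", "easy", "classic", "creamy", "garlic", "lemon", "honey",
  "glazed", "smoked", "fried", "slow", "cooker", "homemade", "crispy",
  "stuffed", "marinated", "skillet", "chowder", "tacos", "noodle", "rice",
  "sandwich", "burger", "pasta", "teriyaki", "barbecue", "herb", "pepper",
  "mustard", "maple", "sesame"
)

#' Generate a synthetic recipe corpus
#'
#' Emulates a recipe website corpus restricted to recipes containing at least
#' one of the 12 study foods. Each recipe has 1-3 ingredients drawn from the
#' food list (the first by the configured ingredient weights, the rest
#' uniformly among the remaining foods) and a title built from its
#' ingredient names plus one or two filler tokens, so a token matcher can
#' recover the ingredients from a query for the title.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `recipe_id`, `title` (space-separated
#'   normalized tokens) and `ingredients` (list column of food names).
#' @export
simulate_recipes <- function(config) {
  stopifnot(inherits(config, "cob12_config"))
  foods <- food_order()
  n <- config$n_recipes
  with_seed_offset(config$seed, 101L, {
    n_ing <- sample(1:3, n, replace = TRUE, prob = c(0.30, 0.45, 0.25))
    first <- sample(foods, n, replace = TRUE, prob = config$ingredient_weights)
    extra <- lapply(seq_len(n), function(i) {
      k <- n_ing[i] - 1L
      if (k == 0L) character(0) else sample(setdiff(foods, first[i]), k)
    })
    n_fill <- sample(1:2, n, replace = TRUE, prob = c(0.4, 0.6))
    fillers <- lapply(n_fill, function(k) sample(recipe_fillers, k))
    ingredients <- Map(c, first, extra)
    title <- vapply(
      seq_len(n),
      function(i) paste(c(ingredients[[i]], fillers[[i]]), collapse = " "),
      character(1)
    )
    tibble::tibble(
      recipe_id = sprintf("r%05d", seq_len(n)),
      title = title,
      ingredients = unname(ingredients)
    )
  })
}

# long (recipe_id, food) table from a corpus
recipe_ingredients_long <- function(recipes) {
  tibble::tibble(
    recipe_id = rep(recipes$recipe_id, lengths(recipes$ingredients)),
    food = unlist(recipes$ingredients, use.names = FALSE)
  )
}

# long (recipe_id, token) table of distinct title tokens, plus token counts
recipe_token_index <- function(recipes) {
  toks <- tokenize(recipes$title)
  long <- tibble::tibble(
    recipe_id = rep(recipes$recipe_id, lengths(toks)),
    token = unlist(toks, use.names = FALSE)
  )
  long <- dplyr::distinct(long)
  n_tok <- dplyr::count(long, .data$recipe_id, name = "n_tokens")
  list(long = long, n_tokens = n_tok)
}
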