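# shared fixtures, all built in code

# a tiny handmade corpus exercising overlap and tie-breaking
tiny_recipes <- function() {
  tibble::tibble(
    recipe_id = c("r001", "r002", "r003", "r004"),
    title = c("chicken soup", "beef egg pie", "chicken", "salmon grilled"),
    ingredients = list(
      "chicken", c("beef", "egg"), "chicken", "salmon"
    )
  )
}

# a profile table from an explicit count matrix and flags
toy_profiles <- function(counts, ...) {
  foods <- cob12::food_reference()$food
  stopifnot(ncol(counts) == 12)
  colnames(counts) <- foods
  out <- dplyr::bind_cols(
    tibble::tibble(
      user_id = sprintf("u%03d", seq_len(nrow(counts))),
      region = 0L
    ),
    tibble::as_tibble(as.data.frame(counts))
  )
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# small default-style config for fast simulation tests
small_config <- function(seed, n_users = 3000, n_recipes = 600, ...) {
  cob12::sim_config(
    seed = seed, n_users = n_users, n_recipes = n_recipes, ...
  )
}

# merge two user-profile tables as if aggregated separately per chunk:
# counts add, flags OR, region recomputed is not possible -> keep first
combine_profiles <- function(a, b) {
  foods <- cob12::food_reference()$food
  flag_cols <- grep("^ask", names(a), value = TRUE)
  all_users <- sort(union(a$user_id, b$user_id))
  template <- a[0, ]
  pick <- function(tab, u) tab[match(u, tab$user_id), , drop = FALSE]
  ra <- pick(a, all_users)
  rb <- pick(b, all_users)
  out <- tibble::tibble(user_id = all_users)
  out$region <- dplyr::coalesce(ra$region, rb$region)
  for (f in foods) {
    out[[f]] <- dplyr::coalesce(ra[[f]], 0L) + dplyr::coalesce(rb[[f]], 0L)
  }
  for (f in flag_cols) {
    out[[f]] <- dplyr::coalesce(ra[[f]], FALSE) | dplyr::coalesce(rb[[f]], FALSE)
  }
  out[names(template)]
}
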