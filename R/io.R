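#' Read and write the package's plain-text interchange formats
#'
#' The query log travels as tab-separated text with columns `user_id`,
#' `text`, `region` (one event per line, UTF-8; header optional on write);
#' recipe corpora, term lexicons, user profiles and the small reference
#' tables travel as comma-separated text with a header. Recipe ingredient
#' lists are serialized as `;`-separated food names.
#'
#' @param events,recipes,lexicon,profiles Tables to write.
#' @param path File path.
#' @param header Whether to write a header line on the log.
#' @return Readers return tibbles; writers return the input invisibly.
#' @name cob12_io
NULL

#' @rdname cob12_io
#' @export
write_search_log <- function(events, path, header = TRUE) {
  out <- dplyr::select(events, "user_id", "text", "region")
  readr::write_tsv(out, path, col_names = header)
  invisible(events)
}

#' @rdname cob12_io
#' @export
read_search_log <- function(path, header = TRUE) {
  cols <- c("user_id", "text", "region")
  ev <- readr::read_tsv(
    path,
    col_names = if (header) TRUE else cols,
    col_types = readr::cols(
      user_id = readr::col_character(),
      text = readr::col_character(),
      region = readr::col_integer()
    ),
    progress = FALSE
  )
  ev$event_id <- seq_len(nrow(ev))
  dplyr::select(ev, "event_id", "user_id", "text", "region")
}

#' @rdname cob12_io
#' @export
write_recipes <- function(recipes, path) {
  out <- tibble::tibble(
    recipe_id = recipes$recipe_id,
    title = recipes$title,
    ingredients = vapply(
      recipes$ingredients, paste, character(1), collapse = ";"
    )
  )
  readr::write_csv(out, path)
  invisible(recipes)
}

#' @rdname cob12_io
#' @export
read_recipes <- function(path) {
  raw <- readr::read_csv(path, col_types = "ccc", progress = FALSE)
  raw$ingredients <- strsplit(raw$ingredients, ";", fixed = TRUE)
  raw
}

#' @rdname cob12_io
#' @export
write_lexicon <- function(lexicon, path) {
  readr::write_csv(lexicon, path)
  invisible(lexicon)
}

#' @rdname cob12_io
#' @export
read_lexicon <- function(path) {
  lex <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  stopifnot(all(c("term", "set") %in% names(lex)))
  if (!"is_drug" %in% names(lex)) lex$is_drug <- TRUE
  lex
}

#' @rdname cob12_io
#' @export
write_profiles <- function(profiles, path) {
  out <- dplyr::mutate(
    profiles, dplyr::across(dplyr::where(is.logical), as.integer)
  )
  readr::write_csv(out, path)
  invisible(profiles)
}

#' @rdname cob12_io
#' @export
read_profiles <- function(path) {
  prof <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  flag_cols <- c(
    grep("^asked_", names(prof), value = TRUE),
    grep("^ask_", names(prof), value = TRUE)
  )
  dplyr::mutate(prof, dplyr::across(dplyr::all_of(flag_cols), as.logical))
}
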