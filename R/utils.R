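#' @importFrom rlang .data
#' @importFrom ggplot2 autoplot
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# run code under a deterministic seed derived from (seed, offset), restoring
# the caller's RNG state afterwards
with_seed_offset <- function(seed, offset, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  derived <- as.integer((as.double(seed) + offset) %% .Machine$integer.max)
  withr::with_seed(derived, code)
}

# Dirichlet draws: n rows, concentration vector alpha
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(
    stats::rgamma(n * k, shape = rep(alpha, each = n), rate = 1),
    nrow = n, ncol = k
  )
  g / rowSums(g)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()] fixing the variant used for
#' every group contrast in the package: the exact null distribution when both
#' samples have at most 10 observations and there are no ties, otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples.
#' @return Two-sided p-value.
#' @keywords internal
rank_sum_p <- function(x, y) {
  small <- min(length(x), length(y)) <= 10
  no_ties <- !anyDuplicated(c(x, y))
  if (small && no_ties) {
    stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
}

#' Normalize query text
#'
#' Lowercases, maps "b-12"/"b 12" spellings to the token "b12", strips
#' punctuation and collapses whitespace. All matching in the package operates
#' on normalized text.
#'
#' @param x Character vector of raw query texts.
#' @return Character vector of normalized texts.
#' @export
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("\\bb[- ]?12\\b", "b12", x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

# split normalized text into tokens; returns a list of character vectors
tokenize <- function(x) strsplit(x, " ", fixed = TRUE)

# average-rank transform
avg_rank <- function(x) rank(x, ties.method = "average")
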