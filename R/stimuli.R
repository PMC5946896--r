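#' Levenshtein edit distance
#'
#' Minimal number of single-character insertions, deletions and substitutions
#' turning one string into the other (computed with [utils::adist()]).
#' Vectorised elementwise with recycling.
#'
#' @param a,b character vectors.
#' @return integer vector of edit counts.
#' @examples
#' levenshtein("maan", "lune")   # 4
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- as.integer(utils::adist(a[i], b[i])[1, 1])
  out
}

#' Normalised Levenshtein distance
#'
#' Edit distance divided by the length of the longer word, giving a lexical
#' overlap score in \[0, 1\]: 1 means the words share no alignable
#' characters. Comparison is case-folded but accent-preserving. Translation
#' equivalents intended for cross-language decoding designs should score 1.0
#' so that above-chance transfer cannot ride on orthographic overlap.
#'
#' @inheritParams levenshtein
#' @return numeric vector in \[0, 1\].
#' @examples
#' normalized_levenshtein("maan", "lune")     # 1
#' normalized_levenshtein("paard", "cheval")  # 1
#' @export
normalized_levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  if (any(nchar(a) == 0 & nchar(b) == 0))
    abort("normalized Levenshtein is undefined when both strings are empty")
  levenshtein(tolower(a), tolower(b)) / pmax(nchar(a), nchar(b))
}

# Built-in Dutch/French translation-equivalent pairs. The first two are the
# concrete pairs any zero-overlap stimulus list starts from; the rest are
# synthetic fillers built over disjoint letter sets (disjoint alphabets force
# the edit distance to equal the longer length, i.e. normalised distance 1).
builtin_pairs <- function() {
  tibble(
    word_l1 = c("maan", "paard"),
    word_l2 = c("lune", "cheval")
  )
}

synthetic_filler_pairs <- function(n) {
  if (n <= 0) return(tibble(word_l1 = character(), word_l2 = character()))
  a_letters <- c("b", "d", "g", "k", "m", "o", "p", "r", "s", "t")
  b_letters <- c("c", "e", "f", "h", "i", "l", "n", "u", "v", "w")
  # base-10 encoding over an alphabet: injective, so filler words are unique
  encode <- function(i, alphabet, min_len) {
    digits <- integer(0)
    while (i > 0) { digits <- c(i %% 10, digits); i <- i %/% 10 }
    digits <- c(rep(0L, max(0L, min_len - length(digits))), digits)
    paste0(alphabet[digits + 1], collapse = "")
  }
  tibble(
    word_l1 = vapply(seq_len(n), function(i) encode(i, a_letters, 4 + i %% 3), ""),
    word_l2 = vapply(seq_len(n), function(i) encode(i, b_letters, 5 + i %% 2), "")
  )
}

#' Generate a zero-lexical-overlap stimulus set
#'
#' Returns `n_concepts` translation pairs: the built-in Dutch/French pairs
#' (maan/lune, paard/cheval) first, then synthetic zero-overlap fillers drawn
#' from disjoint letter sets. Every returned pair has normalised Levenshtein
#' distance exactly 1.
#'
#' @param n_concepts number of concept pairs (0 allowed, returning an empty
#'   set).
#' @return tibble with columns `concept_id`, `word_l1`, `word_l2`.
#' @export
generate_stimulus_set <- function(n_concepts) {
  n_concepts <- as.integer(n_concepts)
  if (is.na(n_concepts) || n_concepts < 0)
    abort("`n_concepts` must be a non-negative integer")
  base <- builtin_pairs()
  out <- dplyr::bind_rows(
    head(base, n_concepts),
    synthetic_filler_pairs(max(0L, n_concepts - nrow(base)))
  )
  out <- dplyr::mutate(out, concept_id = dplyr::row_number(),
                       .before = "word_l1")
  stopifnot(all(normalized_levenshtein(out$word_l1, out$word_l2) == 1))
  out
}

#' Validate a stimulus set's lexical-overlap constraint
#'
#' Computes the (normalised) Levenshtein distance for every translation pair
#' and flags any pair whose distance falls below the required threshold
#' `1 - max_overlap`. With the default `max_overlap = 0` every pair must have
#' distance exactly 1 (no lexical overlap at all).
#'
#' @param pairs data frame with columns `word_l1`, `word_l2` (and optionally
#'   `concept_id`), e.g. from [generate_stimulus_set()].
#' @param max_overlap allowed overlap fraction, default 0.
#' @return A tibble (class `stimulus_report`) with per-pair `distance`,
#'   `norm_distance` and `flagged`; summary statistics are available via
#'   [glance()].
#' @examples
#' validate_stimulus_set(generate_stimulus_set(10))
#' @export
validate_stimulus_set <- function(pairs, max_overlap = 0) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) abort("`pairs` must contain at least one pair")
  if (!all(c("word_l1", "word_l2") %in% names(pairs)))
    abort("`pairs` needs columns `word_l1` and `word_l2`")
  if (any(nchar(pairs$word_l1) == 0) || any(nchar(pairs$word_l2) == 0))
    abort("words must be non-empty")
  if (max_overlap < 0 || max_overlap >= 1)
    abort("`max_overlap` must be in [0, 1)")
  out <- dplyr::mutate(
    pairs,
    distance = levenshtein(tolower(.data$word_l1), tolower(.data$word_l2)),
    norm_distance = normalized_levenshtein(.data$word_l1, .data$word_l2),
    flagged = .data$norm_distance < 1 - max_overlap
  )
  class(out) <- c("stimulus_report", class(out))
  attr(out, "threshold") <- 1 - max_overlap
  out
}

#' @rdname validate_stimulus_set
#' @param x a `stimulus_report`.
#' @param ... unused.
#' @export
glance.stimulus_report <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    mean_distance = mean(x$norm_distance),
    sd_distance = sd(x$norm_distance),
    n_flagged = sum(x$flagged)
  )
}
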