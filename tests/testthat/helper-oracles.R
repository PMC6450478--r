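# Independent brute-force oracles. These enumerate candidate patterns
# exhaustively and check containment/utility by trying every embedding;
# they share no code path with the miners they validate.

# all non-empty subsets of an alphabet, as sorted character vectors
all_subsets <- function(alphabet) {
  unlist(
    purrr::map(seq_along(alphabet), ~ utils::combn(sort(alphabet), .x, simplify = FALSE)),
    recursive = FALSE
  )
}

# --- frequent itemsets -------------------------------------------------

oracle_frequent_itemsets <- function(items_list, min_support) {
  n <- length(items_list)
  min_count <- max(1L, as.integer(ceiling(min_support * n)))
  alphabet <- sort(unique(unlist(items_list)))
  cands <- all_subsets(alphabet)
  counts <- purrr::map_int(cands, function(set) {
    sum(purrr::map_lgl(items_list, ~ all(set %in% .x)))
  })
  keep <- counts >= min_count
  tibble::tibble(
    pattern = purrr::map_chr(cands[keep], ~ paste(.x, collapse = "|")),
    support_count = counts[keep]
  ) |> dplyr::arrange(pattern)
}

# --- sequential patterns ----------------------------------------------

# containment by exhaustive embedding search (tries every element mapping,
# not just the earliest one)
contains_bf <- function(sequence, pattern, from = 1L) {
  if (!length(pattern)) return(TRUE)
  for (j in seq(from, length.out = max(0L, length(sequence) - from + 1L))) {
    if (all(pattern[[1]] %in% names_or_self_bf(sequence[[j]])) &&
        contains_bf(sequence, pattern[-1], j + 1L)) {
      return(TRUE)
    }
  }
  FALSE
}

names_or_self_bf <- function(e) if (is.numeric(e)) names(e) else e

# every sequence of non-empty subsets with at most max_len total items
all_candidate_sequences <- function(alphabet, max_len) {
  subsets <- all_subsets(alphabet)
  sizes <- lengths(subsets)
  grow <- function(prefix, used) {
    out <- list()
    for (i in seq_along(subsets)) {
      if (used + sizes[i] > max_len) next
      cand <- c(prefix, list(subsets[[i]]))
      out <- c(out, list(cand), grow(cand, used + sizes[i]))
    }
    out
  }
  grow(list(), 0L)
}

oracle_sequential_patterns <- function(sequences, min_support, max_len) {
  n <- length(sequences)
  min_count <- max(1L, as.integer(ceiling(min_support * n)))
  alphabet <- sort(unique(unlist(sequences)))
  cands <- all_candidate_sequences(alphabet, max_len)
  counts <- purrr::map_int(cands, function(p) {
    sum(purrr::map_lgl(sequences, ~ contains_bf(.x, p)))
  })
  keep <- counts >= min_count
  tibble::tibble(
    pattern = purrr::map_chr(cands[keep], render_sequence),
    support_count = counts[keep]
  ) |> dplyr::arrange(pattern)
}

# --- high-utility sequential patterns ----------------------------------

# max embedding utility by exhaustive recursion over all embeddings
best_embedding_utility <- function(sequence, pattern, from = 1L) {
  if (!length(pattern)) return(0)
  best <- -Inf
  for (j in seq(from, length.out = max(0L, length(sequence) - from + 1L))) {
    e <- sequence[[j]]
    pos <- match(pattern[[1]], names(e))
    if (!anyNA(pos)) {
      rest <- best_embedding_utility(sequence, pattern[-1], j + 1L)
      if (is.finite(rest)) best <- max(best, sum(e[pos]) + rest)
    }
  }
  best
}

oracle_pattern_utility <- function(sequences, pattern) {
  per <- purrr::map_dbl(sequences, ~ best_embedding_utility(.x, pattern))
  sum(per[is.finite(per)])
}

oracle_high_utility <- function(sequences, min_utility, max_len) {
  alphabet <- sort(unique(unlist(purrr::map(sequences, ~ purrr::map(.x, names)))))
  cands <- all_candidate_sequences(alphabet, max_len)
  utils <- purrr::map_dbl(cands, ~ oracle_pattern_utility(sequences, .x))
  keep <- utils >= min_utility
  tibble::tibble(
    pattern = purrr::map_chr(cands[keep], render_sequence),
    utility = utils[keep]
  ) |> dplyr::arrange(pattern)
}
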