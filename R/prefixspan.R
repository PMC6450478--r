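#' Mine sequential medication patterns (PrefixSpan)
#'
#' A from-scratch PrefixSpan implementation. Patterns are grown depth-first
#' from frequent single items by item extension (adding an item to the last
#' element, i.e. same-day co-administration) and sequence extension
#' (appending a new element, i.e. a later day), with support counted on
#' projected databases. Projection is positional: for every supporting
#' sequence the earliest end position of the current prefix (and of the
#' prefix without its last element) is carried, which is exactly the
#' information needed to count both extension types; globally infrequent
#' items are removed up front (any pattern containing one is itself
#' infrequent). The result is complete and sound: a pattern is returned iff
#' its support reaches `min_support` and it has at most `max_length` items
#' in total.
#'
#' A sequence contains a pattern iff there is an order-preserving mapping of
#' pattern elements into sequence elements with element-wise set inclusion
#' (see [seq_contains()]).
#'
#' @param db A `sequence_db` (see [build_sequence_db()]).
#' @param min_support Minimum relative support in `(0, 1]`; the absolute
#'   threshold is `ceiling(min_support * n_sequences)`.
#' @param max_length Maximum total number of items in a pattern; bounds the
#'   search on adversarial inputs.
#' @param min_size Smallest total item count to report.
#' @param by_age_group Mine each age stratum separately.
#' @return A `med_patterns` tibble with list-column `elements` (each a list
#'   of sorted character vectors), a canonical `pattern` rendering such as
#'   `<(A, B), D>`, `support_count` and `support`.
#' @export
mine_sequential_patterns <- function(db, min_support = 0.15, max_length = 8L,
                                     min_size = 1L, by_age_group = FALSE) {
  check_min_support(min_support)
  if (by_age_group) {
    return(mine_by_group(db, function(sub) {
      mine_sequential_patterns(sub, min_support, max_length, min_size,
                               by_age_group = FALSE)
    }))
  }
  n <- nrow(db)
  if (n == 0) {
    warn("empty sequence database; no patterns mined")
    return(empty_seq_patterns("prefixspan", min_support, 0L))
  }
  min_count <- max(1L, as.integer(ceiling(min_support * n)))

  # frequent items only: a pattern containing an infrequent item is
  # infrequent, so dropping them up front is lossless
  item_support <- table(unlist(purrr::map(db$elements, ~ unique(unlist(.x)))))
  item_names <- sort(names(item_support)[item_support >= min_count])
  K <- length(item_names)
  if (K == 0) {
    return(empty_seq_patterns("prefixspan", min_support, n))
  }
  env <- ps_environment(db$elements, item_names, K)
  env$min_count <- min_count
  env$max_length <- as.integer(max_length)
  acc <- new.env(parent = emptyenv())
  acc$elements <- list()
  acc$counts <- integer(0)
  env$acc <- acc

  states <- ps_initial_states(env)
  for (it in seq_len(K)) {
    sup <- which(states$first[it, ] > 0L)
    if (length(sup) >= min_count) {
      ps_grow(
        list(it),
        list(sids = sup,
             ee_prev = rep(0L, length(sup)),
             ee_full = states$first[it, sup]),
        env
      )
    }
  }
  build_seq_result(acc, item_names, n, min_size, "prefixspan",
                   min_support = min_support)
}

# shared projection scaffolding: integer-coded elements plus flattened
# (item, element-index) arrays per sequence, in element order
ps_environment <- function(elements, item_names, K) {
  env <- new.env(parent = emptyenv())
  env$K <- K
  env$seq_elems <- purrr::map(elements, function(els) {
    coded <- purrr::map(els, ~ sort(match(.x, item_names)[!is.na(match(.x, item_names))]))
    coded[lengths(coded) > 0]
  })
  env$flat_item <- purrr::map(env$seq_elems, ~ as.integer(unlist(.x)))
  env$flat_elem <- purrr::map(env$seq_elems, function(els) {
    rep(seq_along(els), lengths(els))
  })
  env$n_seq <- length(env$seq_elems)
  env
}

# first occurrence element index of every item in every sequence (0 = absent)
ps_initial_states <- function(env) {
  first <- matrix(0L, nrow = env$K, ncol = env$n_seq)
  for (s in seq_len(env$n_seq)) {
    fi <- env$flat_item[[s]]
    fe <- env$flat_elem[[s]]
    d <- !duplicated(fi)
    first[fi[d], s] <- fe[d]
  }
  list(first = first)
}

# depth-first growth; `pattern` is a list of ascending integer vectors,
# `states` holds (sids, ee_prev, ee_full) for every supporting sequence
ps_grow <- function(pattern, states, env) {
  env$acc$elements <- c(env$acc$elements, list(pattern))
  env$acc$counts <- c(env$acc$counts, length(states$sids))
  total <- sum(lengths(pattern))
  if (total >= env$max_length) return(invisible())

  X <- pattern[[length(pattern)]]
  last <- X[length(X)]
  n_sup <- length(states$sids)
  K <- env$K

  # ---- item (I-) extensions: items > last joining the last element
  ee_i <- matrix(0L, nrow = K, ncol = n_sup)
  for (k in seq_len(n_sup)) {
    s <- states$sids[k]
    fi <- env$flat_item[[s]]
    fe <- env$flat_elem[[s]]
    js <- fe[fi == last & fe > states$ee_prev[k]]
    if (length(X) > 1 && length(js)) {
      els <- env$seq_elems[[s]]
      js <- js[purrr::map_lgl(js, ~ all(X %in% els[[.x]]))]
    }
    if (length(js)) {
      sel <- (fe %in% js) & fi > last
      si <- fi[sel]; se <- fe[sel]
      d <- !duplicated(si)
      ee_i[si[d], k] <- se[d]
    }
  }
  i_counts <- rowSums(ee_i > 0L)
  for (it in which(i_counts >= env$min_count)) {
    sup <- which(ee_i[it, ] > 0L)
    new_pattern <- pattern
    new_pattern[[length(new_pattern)]] <- c(X, it)
    ps_grow(
      new_pattern,
      list(sids = states$sids[sup],
           ee_prev = states$ee_prev[sup],
           ee_full = ee_i[it, sup]),
      env
    )
  }

  # ---- sequence (S-) extensions: a new element strictly after the end
  ee_s <- matrix(0L, nrow = K, ncol = n_sup)
  for (k in seq_len(n_sup)) {
    s <- states$sids[k]
    fi <- env$flat_item[[s]]
    fe <- env$flat_elem[[s]]
    sel <- fe > states$ee_full[k]
    si <- fi[sel]; se <- fe[sel]
    d <- !duplicated(si)
    ee_s[si[d], k] <- se[d]
  }
  s_counts <- rowSums(ee_s > 0L)
  for (it in which(s_counts >= env$min_count)) {
    sup <- which(ee_s[it, ] > 0L)
    ps_grow(
      c(pattern, list(it)),
      list(sids = states$sids[sup],
           ee_prev = states$ee_full[sup],
           ee_full = ee_s[it, sup]),
      env
    )
  }
  invisible()
}

build_seq_result <- function(acc, item_names, n, min_size, algorithm,
                             min_support = NULL, min_utility = NULL,
                             utilities = NULL) {
  elements <- purrr::map(acc$elements, function(p) {
    purrr::map(p, ~ item_names[.x])
  })
  out <- tibble(
    elements = elements,
    support_count = as.integer(acc$counts)
  )
  if (!is.null(utilities)) out$utility <- utilities
  out <- out[purrr::map_int(out$elements, ~ sum(lengths(.x))) >= min_size, , drop = FALSE]
  out$pattern <- purrr::map_chr(out$elements, render_sequence)
  out$support <- out$support_count / n
  if ("utility" %in% names(out)) {
    out <- out[order(-out$utility, -out$support_count, out$pattern),
               c("pattern", "elements", "utility", "support_count", "support")]
  } else {
    out <- out[order(-out$support_count, out$pattern),
               c("pattern", "elements", "support_count", "support")]
  }
  as_med_patterns(out, algorithm, min_support = min_support,
                  min_utility = min_utility, n_transactions = n)
}

empty_seq_patterns <- function(algorithm, min_support = NULL, n = 0L,
                               min_utility = NULL, utility = FALSE) {
  if (utility) {
    out <- tibble(
      pattern = character(), elements = list(), utility = double(),
      support_count = integer(), support = double()
    )
  } else {
    out <- tibble(
      pattern = character(), elements = list(),
      support_count = integer(), support = double()
    )
  }
  as_med_patterns(out, algorithm, min_support = min_support,
                  min_utility = min_utility, n_transactions = n)
}

#' Render a sequential pattern
#'
#' Canonical text form: elements in temporal order, multi-item elements in
#' parentheses with items sorted, e.g. `<(A, B), D, A, B>`.
#'
#' @param elements A list of character vectors.
#' @return A single string.
#' @export
render_sequence <- function(elements) {
  parts <- purrr::map_chr(elements, function(e) {
    e <- sort(e)
    if (length(e) > 1) paste0("(", paste(e, collapse = ", "), ")") else e
  })
  paste0("<", paste(parts, collapse = ", "), ">")
}

#' Sequence containment
#'
#' `TRUE` iff `pattern` is contained in `sequence`: there is a strictly
#' order-preserving mapping of pattern elements onto sequence elements with
#' element-wise set inclusion. Matching is greedy-earliest, which is exact
#' for existence.
#'
#' @param sequence A list of character vectors (one per day).
#' @param pattern A list of character vectors (the candidate subsequence).
#' @return Logical scalar.
#' @examples
#' seq_contains(list(c("A", "B"), "C"), list("A", "C")) # TRUE
#' seq_contains(list("C", c("A", "B")), list("A", "C")) # FALSE
#' @export
seq_contains <- function(sequence, pattern) {
  j <- 0L
  for (x in pattern) {
    j <- first_element_containing_chr(sequence, x, j + 1L)
    if (is.na(j)) return(FALSE)
  }
  TRUE
}

first_element_containing_chr <- function(elements, itemset, from) {
  for (j in seq(from, length.out = max(0L, length(elements) - from + 1L))) {
    if (all(itemset %in% names_or_self(elements[[j]]))) return(j)
  }
  NA_integer_
}

# utility-sequence elements are named numeric vectors; plain sequences are
# character vectors
names_or_self <- function(e) if (is.numeric(e)) names(e) else e

#' Mean day gap of a two-element sequential pattern
#'
#' For every sequence supporting a two-element pattern, takes the calendar
#' day of the earliest element matching the second pattern element after the
#' earliest match of the first, minus the day of that first match; returns
#' the mean over supporting sequences. This quantifies the typical spacing
#' of e.g. a medication switch ("A followed, days later, by B").
#'
#' @param db A `sequence_db`.
#' @param pattern A list of exactly two character vectors (or a character
#'   vector of length two, one item per element).
#' @return A one-row tibble with `pattern`, `support_count` and
#'   `mean_gap_days` (`NA` when no sequence supports the pattern).
#' @export
mean_time_gap <- function(db, pattern) {
  if (is.character(pattern)) pattern <- as.list(pattern)
  pattern <- purrr::map(pattern, as.character)
  if (length(pattern) != 2) {
    abort("pattern must have exactly two elements")
  }
  gaps <- purrr::map2_dbl(db$elements, db$days, function(els, days) {
    j1 <- first_element_containing_chr(els, pattern[[1]], 1L)
    if (is.na(j1)) return(NA_real_)
    j2 <- first_element_containing_chr(els, pattern[[2]], j1 + 1L)
    if (is.na(j2)) return(NA_real_)
    as.numeric(days[j2] - days[j1])
  })
  gaps <- gaps[!is.na(gaps)]
  tibble(
    pattern = render_sequence(pattern),
    support_count = length(gaps),
    mean_gap_days = if (length(gaps)) mean(gaps) else NA_real_
  )
}
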