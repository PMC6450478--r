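#' Mine high-utility sequential patterns (USpan)
#'
#' A from-scratch implementation of the USpan algorithm for high-utility
#' sequential-pattern mining. A pattern's utility in one sequence is the
#' maximum, over all embeddings (order-preserving element mappings with set
#' inclusion), of the summed utilities of the embedded items; its database
#' utility is the sum of these maxima over all supporting sequences. Unlike
#' support, utility is not anti-monotone, so the search is pruned with two
#' provably safe bounds:
#'
#' * width pruning — the sequence-weighted utility (SWU: the total utility
#'   of every sequence containing an item/pattern) upper-bounds the utility
#'   of any pattern using that item; globally unpromising items are removed
#'   up front and every candidate extension is SWU-screened before its
#'   projection is built;
#' * depth pruning — a remaining-utility bound: per supporting sequence,
#'   the best embedding utility plus all utility still reachable at or
#'   after the embedding's end; a subtree is abandoned only when the summed
#'   bound falls below `min_utility`.
#'
#' Patterns are grown depth-first by item extension (same element) and
#' sequence extension (later element), exactly as in
#' [mine_sequential_patterns()], with per-sequence dynamic programming over
#' embedding end positions replacing support counting.
#'
#' @param db A `utility_sequence_db` (see [build_utility_db()]).
#' @param min_utility Absolute minimum database utility a pattern must
#'   reach.
#' @param min_utility_rel Alternative relative threshold: a fraction of the
#'   total database utility (useful when scales differ between datasets).
#'   Exactly one of `min_utility` / `min_utility_rel` must be given.
#' @param max_length Maximum total number of items in a pattern.
#' @param by_age_group Mine each age stratum separately (a relative
#'   threshold is then resolved within each stratum).
#' @return A `med_patterns` tibble with list-column `elements`, canonical
#'   `pattern` rendering, `utility`, `support_count` and `support`, ordered
#'   by descending utility with support-count then lexicographic
#'   tie-breaks. Attribute `total_utility` records the database utility
#'   mass.
#' @export
mine_high_utility_sequences <- function(db, min_utility = NULL,
                                        min_utility_rel = NULL,
                                        max_length = 8L,
                                        by_age_group = FALSE) {
  if (is.null(min_utility) == is.null(min_utility_rel)) {
    abort("give exactly one of min_utility or min_utility_rel")
  }
  if (!is.null(min_utility) && min_utility <= 0) {
    abort("min_utility must be > 0")
  }
  if (!is.null(min_utility_rel) &&
      (min_utility_rel <= 0 || min_utility_rel > 1)) {
    abort("min_utility_rel must be in (0, 1]")
  }
  if (by_age_group) {
    return(mine_by_group(db, function(sub) {
      mine_high_utility_sequences(sub, min_utility, min_utility_rel,
                                  max_length, by_age_group = FALSE)
    }))
  }
  n <- nrow(db)
  if (n == 0) {
    warn("empty utility-sequence database; no patterns mined")
    return(empty_seq_patterns("uspan", n = 0L, min_utility = min_utility,
                              utility = TRUE))
  }
  total_utility <- sum(purrr::map_dbl(db$elements, ~ sum(unlist(.x))))
  if (is.null(min_utility)) min_utility <- min_utility_rel * total_utility

  all_names <- sort(unique(unlist(purrr::map(db$elements, ~ purrr::map(.x, names)))))
  su_full <- purrr::map_dbl(db$elements, ~ sum(unlist(.x)))

  # width pruning: SWU of an item bounds the utility of any pattern using it
  swu <- setNames(numeric(length(all_names)), all_names)
  for (s in seq_len(n)) {
    present <- unique(unlist(purrr::map(db$elements[[s]], names)))
    swu[present] <- swu[present] + su_full[s]
  }
  item_names <- all_names[swu[all_names] >= min_utility]
  K <- length(item_names)
  if (K == 0) {
    res <- empty_seq_patterns("uspan", n = n, min_utility = min_utility,
                              utility = TRUE)
    attr(res, "total_utility") <- total_utility
    return(res)
  }

  env <- us_environment(db$elements, item_names, K)
  env$min_utility <- min_utility
  env$max_length <- as.integer(max_length)
  acc <- new.env(parent = emptyenv())
  acc$elements <- list()
  acc$counts <- integer(0)
  acc$utilities <- double(0)
  env$acc <- acc

  for (it in seq_len(K)) {
    states <- us_initial_states(env, it)
    us_grow(list(it), states, env)
  }
  res <- build_seq_result(acc, item_names, n, 1L, "uspan",
                          min_utility = min_utility,
                          utilities = acc$utilities)
  attr(res, "total_utility") <- total_utility
  res
}

# integer-coded, unpromising-item-filtered projection scaffolding; `su`,
# `elemtot` and `sufftot` (remaining utility per element suffix) feed the
# pruning bounds and only count surviving items, which keeps them safe:
# pattern utilities never involve removed items
us_environment <- function(elements, item_names, K) {
  env <- new.env(parent = emptyenv())
  env$K <- K
  env$seq_elems <- purrr::map(elements, function(els) {
    coded <- purrr::map(els, function(e) {
      code <- match(names(e), item_names)
      keep <- !is.na(code)
      o <- order(code[keep])
      list(items = code[keep][o], utils = unname(e)[keep][o])
    })
    coded[purrr::map_int(coded, ~ length(.x$items)) > 0]
  })
  env$flat_item <- purrr::map(env$seq_elems, ~ as.integer(unlist(purrr::map(.x, "items"))))
  env$flat_elem <- purrr::map(env$seq_elems, function(els) {
    rep(seq_along(els), purrr::map_int(els, ~ length(.x$items)))
  })
  env$flat_util <- purrr::map(env$seq_elems, ~ unlist(purrr::map(.x, "utils")))
  env$len <- purrr::map_int(env$seq_elems, length)
  env$su <- purrr::map_dbl(env$flat_util, sum)
  env$elemtot <- purrr::map2(env$flat_util, env$flat_elem, function(u, e) {
    if (!length(u)) return(numeric(0))
    as.numeric(rowsum(u, e))
  })
  env$sufftot <- purrr::map(env$elemtot, ~ rev(cumsum(rev(c(.x, 0)))))
  env$n_seq <- length(env$seq_elems)
  env
}

# g-vectors have length len+1; slot j+1 is embedding-end element j, slot 1
# is the virtual position 0 used by the empty prefix
us_initial_states <- function(env, item) {
  sids <- integer(0); gprev <- list(); gfull <- list()
  for (s in seq_len(env$n_seq)) {
    sel <- env$flat_item[[s]] == item
    if (!any(sel)) next
    len <- env$len[s]
    gf <- rep(-Inf, len + 1)
    gf[env$flat_elem[[s]][sel] + 1L] <- env$flat_util[[s]][sel]
    sids <- c(sids, s)
    gprev <- c(gprev, list(c(0, rep(-Inf, len))))
    gfull <- c(gfull, list(gf))
  }
  list(sids = sids, gprev = gprev, gfull = gfull)
}

# utility of itemset X inside element j of sequence s, NA if not contained
us_elem_utility <- function(env, s, j, X) {
  e <- env$seq_elems[[s]][[j]]
  pos <- match(X, e$items)
  if (anyNA(pos)) NA_real_ else sum(e$utils[pos])
}

us_grow <- function(pattern, states, env) {
  n_sup <- length(states$sids)
  if (n_sup == 0) return(invisible())
  X <- pattern[[length(pattern)]]
  last <- X[length(X)]
  min_utility <- env$min_utility

  utility <- sum(purrr::map_dbl(states$gfull, max))
  if (utility >= min_utility) {
    env$acc$elements <- c(env$acc$elements, list(pattern))
    env$acc$counts <- c(env$acc$counts, n_sup)
    env$acc$utilities <- c(env$acc$utilities, utility)
  }
  if (sum(lengths(pattern)) >= env$max_length) return(invisible())

  # depth pruning: best embedding plus remaining reachable utility
  bound <- 0
  for (k in seq_len(n_sup)) {
    s <- states$sids[k]
    gf <- states$gfull[[k]]
    fin <- which(is.finite(gf))
    js <- fin - 1L
    uX <- purrr::map_dbl(js, ~ us_elem_utility(env, s, .x, X))
    bound <- bound +
      max(gf[fin] - uX + env$elemtot[[s]][js] + env$sufftot[[s]][js + 1L])
  }
  if (bound < min_utility) return(invisible())

  # candidate enumeration (canonical: I-extension items must exceed `last`)
  i_occ <- matrix(FALSE, nrow = env$K, ncol = n_sup)
  s_occ <- matrix(FALSE, nrow = env$K, ncol = n_sup)
  first_prev <- purrr::map_int(states$gprev, ~ which(is.finite(.x))[1] - 1L)
  first_full <- purrr::map_int(states$gfull, ~ which(is.finite(.x))[1] - 1L)
  for (k in seq_len(n_sup)) {
    s <- states$sids[k]
    fi <- env$flat_item[[s]]
    fe <- env$flat_elem[[s]]
    js <- fe[fi == last & fe > first_prev[k]]
    if (length(X) > 1 && length(js)) {
      els <- env$seq_elems[[s]]
      js <- js[purrr::map_lgl(js, ~ all(X %in% els[[.x]]$items))]
    }
    if (length(js)) {
      cand <- unique(fi[(fe %in% js) & fi > last])
      i_occ[cand, k] <- TRUE
    }
    cand <- unique(fi[fe > first_full[k]])
    s_occ[cand, k] <- TRUE
  }
  su_states <- env$su[states$sids]
  i_swu <- as.numeric(i_occ %*% su_states)
  s_swu <- as.numeric(s_occ %*% su_states)

  for (it in which(i_swu >= min_utility)) {
    Xp <- c(X, it)
    new_states <- list(sids = integer(0), gprev = list(), gfull = list())
    for (k in which(i_occ[it, ])) {
      s <- states$sids[k]
      len <- env$len[s]
      gp <- states$gprev[[k]]
      prevbest <- cummax(gp)[seq_len(len)]
      fi <- env$flat_item[[s]]
      fe <- env$flat_elem[[s]]
      js <- fe[fi == it]
      gf <- rep(-Inf, len + 1)
      for (j in js) {
        if (!is.finite(prevbest[j])) next
        u <- us_elem_utility(env, s, j, Xp)
        if (!is.na(u)) gf[j + 1] <- u + prevbest[j]
      }
      if (any(is.finite(gf))) {
        new_states$sids <- c(new_states$sids, s)
        new_states$gprev <- c(new_states$gprev, list(gp))
        new_states$gfull <- c(new_states$gfull, list(gf))
      }
    }
    new_pattern <- pattern
    new_pattern[[length(new_pattern)]] <- Xp
    us_grow(new_pattern, new_states, env)
  }

  for (it in which(s_swu >= min_utility)) {
    new_states <- list(sids = integer(0), gprev = list(), gfull = list())
    for (k in which(s_occ[it, ])) {
      s <- states$sids[k]
      len <- env$len[s]
      gf_old <- states$gfull[[k]]
      base <- cummax(gf_old)[seq_len(len)]
      sel <- env$flat_item[[s]] == it
      js <- env$flat_elem[[s]][sel]
      uu <- env$flat_util[[s]][sel]
      gf <- rep(-Inf, len + 1)
      ok <- is.finite(base[js])
      gf[js[ok] + 1L] <- uu[ok] + base[js[ok]]
      if (any(is.finite(gf))) {
        new_states$sids <- c(new_states$sids, s)
        new_states$gprev <- c(new_states$gprev, list(gf_old))
        new_states$gfull <- c(new_states$gfull, list(gf))
      }
    }
    us_grow(c(pattern, list(it)), new_states, env)
  }
  invisible()
}

#' Database utility of a sequential pattern
#'
#' Evaluates the USpan utility of an arbitrary pattern: per sequence, the
#' maximum embedding utility (dynamic programming over embedding end
#' positions); summed over sequences. Returns 0 for unsupported patterns.
#'
#' @param db A `utility_sequence_db`.
#' @param pattern A list of character vectors (pattern elements), or a
#'   character vector of single-item elements.
#' @return A one-row tibble with `pattern`, `utility` and `support_count`.
#' @export
pattern_utility <- function(db, pattern) {
  if (is.character(pattern)) pattern <- as.list(pattern)
  pattern <- purrr::map(pattern, as.character)
  per_seq <- purrr::map_dbl(db$elements, function(els) {
    len <- length(els)
    best_prev <- c(0, rep(-Inf, len))  # best end < j for current prefix
    for (x in pattern) {
      g <- rep(-Inf, len + 1)
      run <- cummax(best_prev)[seq_len(len)]
      for (j in seq_len(len)) {
        e <- els[[j]]
        pos <- match(x, names(e))
        if (!anyNA(pos) && is.finite(run[j])) g[j + 1] <- sum(e[pos]) + run[j]
      }
      best_prev <- g
    }
    m <- max(best_prev)
    if (is.finite(m)) m else NA_real_
  })
  sup <- sum(!is.na(per_seq))
  tibble(
    pattern = render_sequence(pattern),
    utility = sum(per_seq, na.rm = TRUE),
    support_count = as.integer(sup)
  )
}
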