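#' Mine frequent medication itemsets (FP-Growth)
#'
#' A from-scratch FP-Growth implementation: transactions are compressed into
#' a frequent-pattern tree (items ordered by descending global support,
#' ties broken lexicographically; a header table links equal items), and the
#' complete set of frequent itemsets is mined by recursive conditional-tree
#' growth — no candidate generation. The result is exact: an itemset is
#' returned if and only if its support reaches `min_support`.
#'
#' @param db A `transaction_db` (see [build_transaction_db()]).
#' @param min_support Minimum relative support in `(0, 1]`; the absolute
#'   threshold is `ceiling(min_support * n_transactions)`.
#' @param min_size Smallest itemset size to report (singletons are mined
#'   regardless; set `min_size = 2` to drop them from the output).
#' @param by_age_group If `TRUE`, mine each age stratum separately and add
#'   an `age_group` column; `min_support` then applies within each stratum.
#' @return A `med_patterns` tibble with list-column `items` (sorted), a
#'   canonical `pattern` rendering, `support_count` and `support`, ordered
#'   by descending support then pattern. Attributes: `algorithm`,
#'   `min_support`, `n_transactions`.
#' @examples
#' db <- tibble::tibble(
#'   episode_id = c("p1", "p2"),
#'   age_group = factor(c("0-3m", "0-3m"), levels = age_group_levels()),
#'   items = list(c("A", "B"), c("A", "B"))
#' )
#' mine_frequent_itemsets(db, min_support = 0.5)
#' @export
mine_frequent_itemsets <- function(db, min_support = 0.15, min_size = 1L,
                                   by_age_group = FALSE) {
  check_min_support(min_support)
  if (by_age_group) {
    return(mine_by_group(db, function(sub) {
      mine_frequent_itemsets(sub, min_support, min_size, by_age_group = FALSE)
    }))
  }
  n <- nrow(db)
  if (n == 0) {
    warn("empty transaction database; no patterns mined")
    return(empty_patterns("fpgrowth", min_support, 0L))
  }
  min_count <- max(1L, as.integer(ceiling(min_support * n)))

  counts <- table(unlist(purrr::map(db$items, unique)))
  keep <- names(counts)[counts >= min_count]
  # global item order: descending support_count, lexicographic tie-break
  ord <- order(-as.integer(counts[keep]), keep)
  rank <- setNames(seq_along(keep), keep[ord])

  txns <- purrr::map(db$items, function(it) {
    r <- rank[it[it %in% names(rank)]]
    as.integer(sort(unname(r)))
  })
  tree <- fp_tree(txns, rep(1L, length(txns)), n_items = length(rank))
  found <- fp_mine(tree, min_count, integer(0))

  item_names <- names(rank)
  out <- tibble(
    items = purrr::map(found$itemsets, ~ sort(item_names[.x])),
    support_count = as.integer(found$counts)
  )
  out <- out[lengths(out$items) >= min_size, , drop = FALSE]
  out$pattern <- purrr::map_chr(out$items, render_itemset)
  out$support <- out$support_count / n
  out <- out[order(-out$support_count, out$pattern), c("pattern", "items", "support_count", "support")]
  as_med_patterns(out, "fpgrowth", min_support = min_support, n_transactions = n)
}

# FP-tree: nodes are environments (item, count, parent, children); the
# header table maps each item to the list of its nodes, so the sum of
# counts along an item's chain equals that item's support count.
fp_tree <- function(txns, weights, n_items) {
  root <- new.env(parent = emptyenv())
  root$item <- 0L
  root$count <- 0L
  root$parent <- NULL
  root$children <- list()
  header <- vector("list", n_items)
  for (t in seq_along(txns)) {
    items <- txns[[t]]
    w <- weights[[t]]
    node <- root
    for (it in items) {
      key <- as.character(it)
      child <- node$children[[key]]
      if (is.null(child)) {
        child <- new.env(parent = emptyenv())
        child$item <- it
        child$count <- 0L
        child$parent <- node
        child$children <- list()
        node$children[[key]] <- child
        header[[it]] <- c(header[[it]], child)
      }
      child$count <- child$count + w
      node <- child
    }
  }
  list(root = root, header = header, n_items = n_items)
}

fp_mine <- function(tree, min_count, suffix) {
  itemsets <- list()
  counts <- integer(0)
  # ascending support order (deepest items first), i.e. reverse item rank
  for (it in rev(seq_len(tree$n_items))) {
    chain <- tree$header[[it]]
    if (is.null(chain)) next
    support <- sum(purrr::map_int(chain, ~ .x$count))
    if (support < min_count) next
    pattern <- c(it, suffix)
    itemsets <- c(itemsets, list(pattern))
    counts <- c(counts, support)
    # conditional pattern base: prefix paths above each node in the chain
    cond_txns <- list()
    cond_w <- integer(0)
    for (node in chain) {
      path <- integer(0)
      p <- node$parent
      while (!is.null(p$parent)) {
        path <- c(p$item, path)
        p <- p$parent
      }
      if (length(path)) {
        cond_txns <- c(cond_txns, list(path))
        cond_w <- c(cond_w, node$count)
      }
    }
    if (length(cond_txns)) {
      # keep only items frequent within the conditional base
      csup <- integer(tree$n_items)
      for (k in seq_along(cond_txns)) {
        csup[cond_txns[[k]]] <- csup[cond_txns[[k]]] + cond_w[k]
      }
      frequent <- which(csup >= min_count)
      cond_txns <- purrr::map(cond_txns, ~ .x[.x %in% frequent])
      keep <- lengths(cond_txns) > 0
      if (any(keep)) {
        ctree <- fp_tree(cond_txns[keep], cond_w[keep], tree$n_items)
        sub <- fp_mine(ctree, min_count, pattern)
        itemsets <- c(itemsets, sub$itemsets)
        counts <- c(counts, sub$counts)
      }
    }
  }
  list(itemsets = itemsets, counts = counts)
}

#' Render an itemset
#'
#' Canonical text form of an unordered medication set: items sorted and
#' comma-separated in parentheses, e.g. `(A, B)`.
#'
#' @param items Character vector of item names.
#' @return A single string.
#' @export
render_itemset <- function(items) {
  paste0("(", paste(sort(items), collapse = ", "), ")")
}

check_min_support <- function(min_support) {
  if (!is.numeric(min_support) || length(min_support) != 1 ||
      is.na(min_support) || min_support <= 0 || min_support > 1) {
    abort("min_support must be a single number in (0, 1]")
  }
}

mine_by_group <- function(db, f) {
  groups <- levels(db$age_group)
  present <- groups[groups %in% as.character(db$age_group)]
  res <- purrr::map(present, function(g) {
    sub <- db[as.character(db$age_group) == g, , drop = FALSE]
    r <- f(sub)
    if (nrow(r)) r$age_group <- factor(g, levels = groups)
    r
  })
  out <- bind_rows(res)
  if (!nrow(out)) return(out)
  meta <- attributes(res[[1]])
  as_med_patterns(
    out[c("age_group", setdiff(names(out), "age_group"))],
    meta$algorithm,
    min_support = meta$min_support,
    min_utility = meta$min_utility,
    n_transactions = nrow(db)
  )
}

as_med_patterns <- function(x, algorithm, min_support = NULL,
                            min_utility = NULL, n_transactions = NULL) {
  x <- as_tibble(x)
  class(x) <- c("med_patterns", class(x))
  attr(x, "algorithm") <- algorithm
  attr(x, "min_support") <- min_support
  attr(x, "min_utility") <- min_utility
  attr(x, "n_transactions") <- n_transactions
  x
}

empty_patterns <- function(algorithm, min_support = NULL, n = 0L,
                           min_utility = NULL, utility = FALSE) {
  out <- tibble(
    pattern = character(), items = list(),
    support_count = integer(), support = double()
  )
  if (utility) out$utility <- double()
  as_med_patterns(out, algorithm, min_support = min_support,
                  min_utility = min_utility, n_transactions = n)
}
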