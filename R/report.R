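#' Top-k patterns with deterministic tie-breaking
#'
#' Ranks mined patterns by score — utility for high-utility results, support
#' otherwise — breaking ties by support count and then by the canonical
#' pattern rendering, and keeps the first `min(k, available)` rows. When the
#' input carries an `age_group` column the ranking is applied within each
#' stratum.
#'
#' @param patterns A `med_patterns` tibble from one of the miners.
#' @param k Number of patterns to keep per stratum (default 10).
#' @param min_size Drop patterns with fewer total items before ranking
#'   (e.g. `2` to ignore singletons).
#' @return The ranked subset, with a `rank` column.
#' @export
top_k_patterns <- function(patterns, k = 10L, min_size = 1L) {
  if (k < 1) abort("k must be >= 1")
  score <- if ("utility" %in% names(patterns)) patterns$utility else patterns$support
  sizes <- purrr::map_int(
    if ("elements" %in% names(patterns)) {
      purrr::map(patterns$elements, ~ unlist(.x))
    } else {
      patterns$items
    },
    length
  )
  keep <- sizes >= min_size
  out <- as_tibble(patterns)[keep, , drop = FALSE]
  out$.score <- score[keep]
  grouped <- "age_group" %in% names(out)
  if (grouped) out <- group_by(out, .data$age_group)
  out <- out %>%
    arrange(desc(.data$.score), desc(.data$support_count), .data$pattern,
            .by_group = grouped) %>%
    mutate(rank = row_number()) %>%
    slice_head(n = as.integer(k)) %>%
    ungroup() %>%
    select(-".score")
  meta <- attributes(patterns)
  as_med_patterns(out, meta$algorithm, min_support = meta$min_support,
                  min_utility = meta$min_utility,
                  n_transactions = meta$n_transactions)
}

#' Share of administrations given by a route class
#'
#' The fraction of (cleaned) administration records whose merged route label
#' falls in `routes` — the summary behind route-based treatment patterns
#' such as "x% of records were intravenous".
#'
#' @param records Cleaned administration records.
#' @param routes Character vector of route labels forming the class.
#' @return A one-row tibble with `numerator`, `denominator` and `share`.
#' @export
route_share <- function(records, routes) {
  if (!nrow(records)) abort("route share is undefined on an empty record set")
  num <- sum(records$route %in% routes)
  tibble(
    routes = paste(sort(routes), collapse = "+"),
    numerator = num,
    denominator = nrow(records),
    share = num / nrow(records)
  )
}

#' Per-stratum medication frequency table
#'
#' Counts administration records per medication within each stratum (age
#' group or admission calendar year) and reports per-stratum proportions,
#' plus the overall coverage of the globally most frequent `top_n`
#' medications — the "top-40 medications account for x% of records" style
#' of summary.
#'
#' @param records Cleaned administration records.
#' @param by `"age_group"` or `"calendar_year"`.
#' @param top_n Size of the global head of the frequency distribution whose
#'   record coverage is reported.
#' @return An object of class `frequency_table`: a list with `by_stratum`
#'   (tibble: stratum, medication, n, prop), `overall` (tibble: medication,
#'   n, prop, cumulative), `top_n`, `top_medications` and `top_coverage`.
#' @export
frequency_table <- function(records, by = c("age_group", "calendar_year"),
                            top_n = 40L) {
  by <- match.arg(by)
  stratum <- if (by == "age_group") {
    assign_age_group(records$birth_date, records$admission_date)
  } else {
    factor(format(records$admission_date, "%Y"))
  }
  per <- tibble(stratum = stratum, medication = records$medication) %>%
    count(.data$stratum, .data$medication, name = "n") %>%
    group_by(.data$stratum) %>%
    mutate(prop = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    arrange(.data$stratum, desc(.data$n), .data$medication)
  overall <- records %>%
    count(.data$medication, name = "n") %>%
    arrange(desc(.data$n), .data$medication) %>%
    mutate(prop = .data$n / sum(.data$n), cumulative = cumsum(.data$prop))
  top <- head(overall$medication, top_n)
  structure(
    list(
      by_stratum = per,
      overall = overall,
      top_n = as.integer(top_n),
      top_medications = top,
      top_coverage = sum(overall$prop[seq_along(top)])
    ),
    class = "frequency_table"
  )
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("<frequency_table> ", nrow(x$overall), " medications, ",
      length(unique(x$by_stratum$stratum)), " strata; top ", x$top_n,
      " cover ", sprintf("%.2f%%", 100 * x$top_coverage), " of records\n",
      sep = "")
  invisible(x)
}

#' Fleiss kappa for a fixed-rater rating table
#'
#' Chance-corrected agreement among `n` raters who each assign one of `m`
#' categories to every subject: `kappa = (Pbar - Pe) / (1 - Pe)`, with
#' per-subject agreement `P_i = (sum_j n_ij^2 - n) / (n (n - 1))` and chance
#' agreement `Pe = sum_j p_j^2` from the marginal category proportions.
#'
#' @param table A matrix or data frame of rating counts, subjects in rows
#'   and categories in columns; every row must sum to the same number of
#'   raters. A `subject_id` column, if present, is used for row names.
#' @return A one-row tibble with `kappa`, `n_subjects`, `n_raters`,
#'   `n_categories`, `p_bar` and `p_e`.
#' @examples
#' ratings <- rbind(c(5, 0), c(5, 0), c(0, 5)) # perfect agreement
#' fleiss_kappa(ratings)$kappa # 1
#' @export
fleiss_kappa <- function(table) {
  if (is.data.frame(table)) {
    if ("subject_id" %in% names(table)) {
      table <- as.data.frame(table)
      rownames(table) <- table$subject_id
      table$subject_id <- NULL
    }
    table <- as.matrix(table)
  }
  storage.mode(table) <- "double"
  if (nrow(table) < 2) abort("need at least 2 subjects")
  if (ncol(table) < 2) abort("need at least 2 categories")
  raters <- unique(rowSums(table))
  if (length(raters) != 1) abort("every subject must have the same number of ratings")
  n <- raters
  if (n < 2) abort("need at least 2 raters")
  if (any(table < 0)) abort("rating counts must be non-negative")
  p_j <- colSums(table) / (nrow(table) * n)
  p_i <- (rowSums(table^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  if (1 - p_e < .Machine$double.eps^0.5) {
    abort("chance agreement is 1 (all ratings in a single category); kappa undefined")
  }
  tibble(
    kappa = (p_bar - p_e) / (1 - p_e),
    n_subjects = nrow(table),
    n_raters = as.integer(n),
    n_categories = ncol(table),
    p_bar = p_bar,
    p_e = p_e
  )
}

#' Read a rating table CSV
#'
#' Layout: a `subject_id` column, then one column per category holding the
#' number of raters who assigned that category.
#'
#' @param path CSV path.
#' @return A tibble suitable for [fleiss_kappa()].
#' @export
read_rating_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}

flatten_combination <- function(elements) {
  paste(sort(unique(unlist(elements))), collapse = ", ")
}

#' Cross-algorithm pattern comparison
#'
#' Aligns the top-k patterns of several miners into one table of distinct
#' medication combinations: itemsets are identified by their item set,
#' sequential patterns by their canonical rendering, and a sequence is
#' matched to an itemset through its flattened set of distinct items. Each
#' combination row records, per algorithm and per age group, whether any
#' top-k cell contains it — the machine-readable form of a
#' "pattern x algorithm x age group" checkmark table.
#'
#' @param reports A named list of `med_patterns` tibbles (one per
#'   algorithm, each with an `age_group` column as produced with
#'   `by_age_group = TRUE`); names default to each input's algorithm
#'   attribute.
#' @param k Top-k cutoff applied per (algorithm, age group) cell.
#' @param min_size Minimum total items per pattern (default 2: combinations
#'   involve at least two medications).
#' @return An object of class `pattern_report`: list with `cells` (tibble
#'   algorithm/age_group/rank/pattern/score columns), `combinations`
#'   (tibble: combination, one logical column per algorithm, one per age
#'   group, n_cells), `k` and `n_combinations`.
#' @export
build_comparison <- function(reports, k = 10L, min_size = 2L) {
  if (is.null(names(reports)) || any(names(reports) == "")) {
    names(reports) <- purrr::map_chr(reports, ~ attr(.x, "algorithm") %||% NA_character_)
  }
  if (anyNA(names(reports)) || anyDuplicated(names(reports))) {
    abort("reports must be uniquely named (one per algorithm)")
  }
  cells <- purrr::imap(reports, function(r, alg) {
    if (!"age_group" %in% names(r)) {
      abort("each report must carry an age_group column (mine with by_age_group = TRUE)")
    }
    top <- top_k_patterns(r, k = k, min_size = min_size)
    tibble(
      algorithm = alg,
      age_group = top$age_group,
      rank = top$rank,
      pattern = top$pattern,
      combination = purrr::map_chr(
        if ("elements" %in% names(top)) top$elements else top$items,
        flatten_combination
      ),
      score = if ("utility" %in% names(top)) top$utility else top$support,
      support_count = top$support_count
    )
  }) %>% bind_rows()

  groups <- age_group_levels()
  combos <- cells %>%
    distinct(.data$combination) %>%
    arrange(.data$combination)
  for (alg in names(reports)) {
    combos[[alg]] <- combos$combination %in% cells$combination[cells$algorithm == alg]
  }
  for (g in groups) {
    combos[[g]] <- combos$combination %in%
      cells$combination[as.character(cells$age_group) == g]
  }
  combos$n_cells <- purrr::map_int(
    combos$combination,
    ~ sum(cells$combination == .x)
  )
  structure(
    list(
      cells = cells,
      combinations = combos,
      k = as.integer(k),
      algorithms = names(reports),
      n_combinations = nrow(combos)
    ),
    class = "pattern_report"
  )
}

#' @export
print.pattern_report <- function(x, ...) {
  cat("<pattern_report> ", x$n_combinations, " distinct combinations from ",
      length(x$algorithms), " algorithms x ",
      length(unique(as.character(x$cells$age_group))), " age groups (k = ",
      x$k, ")\n", sep = "")
  invisible(x)
}

#' Write mined patterns as TSV
#'
#' @param patterns A `med_patterns` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patterns_tsv <- function(patterns, path) {
  out <- as_tibble(patterns)
  list_cols <- names(out)[purrr::map_lgl(out, is.list)]
  out <- out[setdiff(names(out), list_cols)]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a pattern report
#'
#' `write_report_tsv()` writes the combination table as TSV;
#' `write_report_json()` writes cells and combinations as JSON.
#'
#' @param report A `pattern_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  readr::write_tsv(report$combinations, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(
      k = report$k,
      n_combinations = report$n_combinations,
      cells = report$cells,
      combinations = report$combinations
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
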