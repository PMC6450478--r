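#' Tidy mined patterns
#'
#' Returns the pattern table as a plain tibble without the list columns,
#' ready for joining, filtering or writing.
#'
#' @param x A `med_patterns` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy med_patterns
#' @export
tidy.med_patterns <- function(x, ...) {
  out <- as_tibble(x)
  out[!purrr::map_lgl(out, is.list)]
}

#' @rdname tidy.med_patterns
#' @method glance med_patterns
#' @export
glance.med_patterns <- function(x, ...) {
  tibble(
    algorithm = attr(x, "algorithm") %||% NA_character_,
    n_patterns = nrow(x),
    n_transactions = attr(x, "n_transactions") %||% NA_integer_,
    min_support = attr(x, "min_support") %||% NA_real_,
    min_utility = attr(x, "min_utility") %||% NA_real_,
    max_score = if (!nrow(x)) NA_real_
                else if ("utility" %in% names(x)) max(x$utility)
                else max(x$support)
  )
}

#' @method tidy pattern_report
#' @export
tidy.pattern_report <- function(x, ...) x$combinations

#' @method glance pattern_report
#' @export
glance.pattern_report <- function(x, ...) {
  tibble(
    n_combinations = x$n_combinations,
    n_algorithms = length(x$algorithms),
    n_age_groups = length(unique(as.character(x$cells$age_group))),
    k = x$k
  )
}

#' @method tidy frequency_table
#' @export
tidy.frequency_table <- function(x, ...) x$by_stratum

#' @method glance frequency_table
#' @export
glance.frequency_table <- function(x, ...) {
  tibble(
    n_medications = nrow(x$overall),
    n_strata = length(unique(x$by_stratum$stratum)),
    top_n = x$top_n,
    top_coverage = x$top_coverage
  )
}

#' Plot mined patterns
#'
#' Horizontal bar chart of the top patterns by score (support or utility),
#' faceted by age group when present.
#'
#' @param object A `med_patterns` tibble.
#' @param k How many patterns to show (per stratum).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot med_patterns
#' @export
autoplot.med_patterns <- function(object, k = 10L, ...) {
  top <- top_k_patterns(object, k = k)
  score_name <- if ("utility" %in% names(top)) "utility" else "support"
  dat <- tidy(top)
  dat$score <- dat[[score_name]]
  p <- ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$pattern, .data$score)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = score_name, y = NULL,
      title = paste0("Top patterns (", attr(object, "algorithm") %||% "?", ")")
    )
  if ("age_group" %in% names(dat)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$age_group), scales = "free")
  }
  p
}

#' Plot a cross-algorithm pattern report
#'
#' Presence/absence tile map: distinct medication combinations against age
#' groups, filled where any algorithm's top-k cell contains the
#' combination.
#'
#' @param object A `pattern_report`.
#' @param max_rows Cap on combinations shown (most widely shared first).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pattern_report
#' @export
autoplot.pattern_report <- function(object, max_rows = 30L, ...) {
  groups <- age_group_levels()
  dat <- object$combinations %>%
    arrange(desc(.data$n_cells), .data$combination) %>%
    slice_head(n = max_rows) %>%
    tidyr::pivot_longer(dplyr::all_of(groups), names_to = "age_group",
                        values_to = "present") %>%
    mutate(age_group = factor(.data$age_group, levels = groups))
  ggplot2::ggplot(dat, ggplot2::aes(.data$age_group, .data$combination,
                                    fill = .data$present)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "white")) +
    ggplot2::labs(x = "age group", y = NULL, fill = "in top-k")
}

#' Plot a medication frequency table
#'
#' @param object A `frequency_table`.
#' @param top_n Medications shown (from the global head).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot frequency_table
#' @export
autoplot.frequency_table <- function(object, top_n = 20L, ...) {
  dat <- head(object$overall, top_n)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$prop,
    y = stats::reorder(.data$medication, .data$prop)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "proportion of records", y = NULL)
}
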