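#' Clean administration records
#'
#' The two cleaning steps applied before any database is built:
#' merge similar route-of-administration labels (via the catalog's
#' route-merge map) and drop diluent/carrier medications (e.g. dextrose 5%
#' in water, normal saline), which are delivery vehicles with no therapeutic
#' intent. Medication names are also (re-)canonicalized, so `clean_records()`
#' is idempotent and safe to call on records built in memory.
#'
#' @param records A record tibble (see [read_admin_records()]).
#' @param catalog A [med_catalog()].
#' @param unknown Policy for medications absent from the catalog:
#'   `"keep"` (default) passes them through with utility `P = 1` and warns
#'   once; `"error"` rejects the run.
#' @return The cleaned tibble with attributes `n_diluents_removed` (count of
#'   dropped rows) and `row_errors` carried over from reading. A
#'   `cleaning_summary()` accessor returns the counts as a one-row tibble.
#' @export
clean_records <- function(records, catalog, unknown = c("keep", "error")) {
  unknown <- match.arg(unknown)
  records <- as_tibble(records)
  errors <- row_errors(records)
  if (nrow(records)) {
    records$medication <- canonicalize_medication(records$medication, catalog)
    records$route <- merge_route(records$route, catalog)
  }
  unknown_meds <- setdiff(unique(records$medication), catalog$medications$name)
  if (length(unknown_meds)) {
    msg <- paste0(
      length(unknown_meds), " medication(s) absent from the catalog",
      " (e.g. ", paste(head(unknown_meds, 3), collapse = ", "), ")"
    )
    if (unknown == "error") abort(msg)
    warn(paste0(msg, "; passed through with P = 1"))
  }
  drop <- is_diluent(records$medication, catalog)
  out <- records[!drop, , drop = FALSE]
  attr(out, "n_diluents_removed") <- sum(drop)
  attr(out, "row_errors") <- errors
  out
}

#' @rdname clean_records
#' @export
cleaning_summary <- function(records) {
  tibble(
    n_records = nrow(records),
    n_diluents_removed = attr(records, "n_diluents_removed") %||% 0L,
    n_row_errors = nrow(row_errors(records))
  )
}

episode_day <- function(records) {
  as.integer(records$admin_date - records$admission_date) + 1L
}

# Per-episode header: id, age group, admission date. Episode order is fixed
# by (age_group, episode_id) so downstream output is deterministic.
episode_index <- function(records) {
  idx <- records %>%
    distinct(.data$episode_id, .data$birth_date, .data$admission_date) %>%
    mutate(age_group = assign_age_group(.data$birth_date, .data$admission_date)) %>%
    distinct(.data$episode_id, .data$age_group) %>%
    arrange(.data$age_group, .data$episode_id)
  attr(idx, "n_diluents_removed") <- NULL
  attr(idx, "row_errors") <- NULL
  idx
}

#' Build a transaction database
#'
#' One transaction per hospitalization episode: the set of distinct
#' medications administered during the stay, with dose and timing discarded
#' (the input form for frequent-itemset mining). Items within a transaction
#' are unique and sorted.
#'
#' @param records Cleaned records (see [clean_records()]).
#' @return A tibble of class `transaction_db` with columns `episode_id`,
#'   `age_group` and list-column `items`.
#' @export
build_transaction_db <- function(records) {
  idx <- episode_index(records)
  items <- split(records$medication, records$episode_id)
  idx$items <- purrr::map(idx$episode_id, ~ sort(unique(items[[.x]])))
  class(idx) <- c("transaction_db", class(idx))
  idx
}

#' Build a sequence database
#'
#' One sequence per hospitalization episode: an ordered list of elements,
#' each element the set of distinct medications administered on the same
#' calendar day, elements in strictly increasing day order (the input form
#' for sequential-pattern mining). Days are counted from admission
#' (admission day = 1).
#'
#' @inheritParams build_transaction_db
#' @return A tibble of class `sequence_db` with columns `episode_id`,
#'   `age_group`, list-column `days` (integer day stamps) and list-column
#'   `elements` (each a list of sorted character vectors).
#' @export
build_sequence_db <- function(records) {
  idx <- episode_index(records)
  records <- records %>% mutate(.day = episode_day(records))
  per_ep <- split(records[c("medication", ".day")], records$episode_id)
  seqs <- purrr::map(idx$episode_id, function(eid) {
    d <- per_ep[[eid]]
    days <- sort(unique(d$.day))
    elements <- purrr::map(days, ~ sort(unique(d$medication[d$.day == .x])))
    list(days = as.integer(days), elements = elements)
  })
  idx$days <- purrr::map(seqs, "days")
  idx$elements <- purrr::map(seqs, "elements")
  class(idx) <- c("sequence_db", class(idx))
  idx
}

#' Build a utility-sequence database
#'
#' Shaped like [build_sequence_db()], but every item in every element carries
#' a medication utility `u = P(i) * q`, where `P(i)` is the catalog's
#' per-dose-unit utility value and `q` is the total dose quantity of that
#' medication on that calendar day within the episode (same-day repeat doses
#' are aggregated into a single item). This is the input form for
#' high-utility sequential-pattern mining.
#'
#' @inheritParams clean_records
#' @param default_P Utility value used for medications absent from the
#'   catalog.
#' @return A tibble of class `utility_sequence_db` with columns `episode_id`,
#'   `age_group`, `days` and list-column `elements` (each a list of named
#'   numeric vectors: names are medications, values are utilities).
#' @export
build_utility_db <- function(records, catalog, default_P = 1) {
  if (any(records$dose_qty < 0)) abort("dose_qty must be >= 0")
  idx <- episode_index(records)
  per_day <- records %>%
    mutate(.day = episode_day(records)) %>%
    group_by(.data$episode_id, .data$.day, .data$medication) %>%
    summarise(q = sum(.data$dose_qty), .groups = "drop") %>%
    mutate(u = utility_value(.data$medication, catalog, default = default_P) * .data$q)
  per_ep <- split(per_day, per_day$episode_id)
  seqs <- purrr::map(idx$episode_id, function(eid) {
    d <- per_ep[[eid]]
    days <- sort(unique(d$.day))
    elements <- purrr::map(days, function(day) {
      e <- d[d$.day == day, ]
      o <- order(e$medication)
      setNames(e$u[o], e$medication[o])
    })
    list(days = as.integer(days), elements = elements)
  })
  idx$days <- purrr::map(seqs, "days")
  idx$elements <- purrr::map(seqs, "elements")
  class(idx) <- c("utility_sequence_db", class(idx))
  idx
}

#' Serialize episode databases as JSON lines
#'
#' One episode per line, for inspection and text fixtures. The three
#' database classes ([build_transaction_db()], [build_sequence_db()],
#' [build_utility_db()]) are all supported and round-trip.
#'
#' @param db A database tibble.
#' @param path Output path.
#' @return `path` invisibly; `read_db_jsonl()` returns the database tibble.
#' @export
write_db_jsonl <- function(db, path) {
  kind <- intersect(class(db), c("transaction_db", "sequence_db", "utility_sequence_db"))[1]
  if (is.na(kind)) abort("not a recognised episode database")
  lines <- purrr::map_chr(seq_len(nrow(db)), function(i) {
    entry <- list(
      kind = kind,
      episode_id = db$episode_id[i],
      age_group = as.character(db$age_group[i])
    )
    if (kind == "transaction_db") {
      entry$items <- db$items[[i]]
    } else {
      entry$days <- db$days[[i]]
      entry$elements <- if (kind == "sequence_db") {
        db$elements[[i]]
      } else {
        purrr::map(db$elements[[i]], as.list)
      }
    }
    jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_db_jsonl
#' @export
read_db_jsonl <- function(path) {
  entries <- purrr::map(readLines(path), jsonlite::fromJSON, simplifyVector = FALSE)
  if (!length(entries)) abort("empty database file")
  kind <- entries[[1]]$kind
  out <- tibble(
    episode_id = purrr::map_chr(entries, "episode_id"),
    age_group = factor(purrr::map_chr(entries, "age_group"), levels = age_group_levels())
  )
  if (kind == "transaction_db") {
    out$items <- purrr::map(entries, ~ as.character(unlist(.x$items)))
  } else {
    out$days <- purrr::map(entries, ~ as.integer(unlist(.x$days)))
    out$elements <- purrr::map(entries, function(e) {
      purrr::map(e$elements, function(el) {
        if (kind == "sequence_db") as.character(unlist(el)) else unlist(el)
      })
    })
  }
  class(out) <- c(kind, class(out))
  out
}
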