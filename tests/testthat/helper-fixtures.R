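# In-code fixtures shared across the suite. Everything is built
# programmatically; no binary data.

# a small catalog: two diluents (with short-name synonyms), a few named
# drugs with utility values, and a route-merge map
tiny_catalog <- function() {
  med_catalog(
    tibble::tibble(
      name = c(
        "DEXTROSE 5% IN WATER", "NORMAL SALINE",
        "CEFOTAXIME", "CEFIXIME", "CEFTRIAXONE", "AZITHROMYCIN",
        "ALBUTEROL", "BUDESONIDE"
      ),
      utility = c(0, 0, 10, 8, 5, 5, 2, 3),
      is_diluent = c(TRUE, TRUE, rep(FALSE, 6)),
      class = c(
        "diluent", "diluent", "antibiotic", "antibiotic", "antibiotic",
        "antibiotic", "antiasthmatic", "corticosteroid"
      )
    ),
    synonyms = c(
      "D5W" = "DEXTROSE 5% IN WATER",
      "NS" = "NORMAL SALINE",
      "CTX" = "CEFOTAXIME"
    ),
    route_merge = c("IV drip" = "IV", "IV push" = "IV", "po" = "oral")
  )
}

# compact administration-record builder: one row per (episode, day, med)
make_records <- function(episode, day, med,
                         dose = 1, route = "IV",
                         admission = as.Date("2015-03-01"),
                         birth = as.Date("2015-01-01"),
                         stay = 30L, sex = "male") {
  n <- max(length(episode), length(day), length(med))
  tibble::tibble(
    episode_id = rep_len(as.character(episode), n),
    patient_sex = rep_len(sex, n),
    birth_date = rep_len(birth, n),
    admission_date = rep_len(admission, n),
    discharge_date = rep_len(admission, n) + stay,
    medication = rep_len(med, n),
    route = rep_len(route, n),
    dose_qty = rep_len(dose, n),
    dose_unit = "mg",
    admin_date = rep_len(admission, n) + rep_len(as.integer(day), n) - 1L
  )
}

# wrap bare item lists into the three database shapes
as_tdb <- function(items, groups = "0-3m") {
  out <- tibble::tibble(
    episode_id = sprintf("e%03d", seq_along(items)),
    age_group = factor(rep_len(groups, length(items)),
                       levels = age_group_levels()),
    items = purrr::map(items, ~ sort(unique(as.character(.x))))
  )
  class(out) <- c("transaction_db", class(out))
  out
}

as_sdb <- function(sequences, groups = "0-3m", days = NULL) {
  out <- tibble::tibble(
    episode_id = sprintf("e%03d", seq_along(sequences)),
    age_group = factor(rep_len(groups, length(sequences)),
                       levels = age_group_levels()),
    days = if (is.null(days)) {
      purrr::map(sequences, ~ seq_along(.x))
    } else {
      purrr::map(days, as.integer)
    },
    elements = purrr::map(sequences, function(s) purrr::map(s, as.character))
  )
  class(out) <- c("sequence_db", class(out))
  out
}

# sequences given as lists of named numeric vectors (name = med, value = u)
as_udb <- function(sequences, groups = "0-3m") {
  out <- tibble::tibble(
    episode_id = sprintf("e%03d", seq_along(sequences)),
    age_group = factor(rep_len(groups, length(sequences)),
                       levels = age_group_levels()),
    days = purrr::map(sequences, ~ seq_along(.x)),
    elements = sequences
  )
  class(out) <- c("utility_sequence_db", class(out))
  out
}

# random small databases for oracle-equivalence and property tests
random_tdb <- function(n_items = 8, n_txn = 10) {
  alphabet <- LETTERS[seq_len(sample(2:n_items, 1))]
  as_tdb(purrr::map(seq_len(sample(2:n_txn, 1)), function(i) {
    sample(alphabet, sample.int(length(alphabet), 1))
  }))
}

random_sdb <- function(n_items = 4, n_seq = 6, n_elem = 4, elem_max = 3) {
  alphabet <- LETTERS[seq_len(sample(2:n_items, 1))]
  as_sdb(purrr::map(seq_len(sample(2:n_seq, 1)), function(i) {
    purrr::map(seq_len(sample.int(n_elem, 1)), function(j) {
      sample(alphabet, sample.int(min(elem_max, length(alphabet)), 1))
    })
  }))
}

random_udb <- function(n_items = 4, n_seq = 5, n_elem = 4, max_util = 20) {
  alphabet <- LETTERS[seq_len(sample(2:n_items, 1))]
  as_udb(purrr::map(seq_len(sample(2:n_seq, 1)), function(i) {
    purrr::map(seq_len(sample.int(n_elem, 1)), function(j) {
      k <- sample.int(min(3, length(alphabet)), 1)
      meds <- sort(sample(alphabet, k))
      stats::setNames(as.numeric(sample.int(max_util, k, replace = TRUE)), meds)
    })
  }))
}

# canonical comparable form of a mined result
pattern_key <- function(res) {
  if ("elements" %in% names(res)) {
    out <- tibble::tibble(pattern = res$pattern, support_count = res$support_count)
  } else {
    out <- tibble::tibble(
      pattern = purrr::map_chr(res$items, ~ paste(sort(.x), collapse = "|")),
      support_count = res$support_count
    )
  }
  dplyr::arrange(out, pattern)
}
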