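test_that("cleaning removes diluents, merges routes and counts removals", {
  cat <- tiny_catalog()
  rec <- make_records(
    episode = "E1", day = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5),
    med = c("D5W", "CEFOTAXIME", "NS", "CEFIXIME", "D5W", "ALBUTEROL",
            "NORMAL SALINE", "BUDESONIDE", "CEFTRIAXONE", "AZITHROMYCIN"),
    route = c("IV drip", "IV push", "IV", "po", "IV", "IV", "IV", "IV",
              "IV", "IV")
  )
  out <- clean_records(rec, cat)
  expect_equal(nrow(out), 6)
  expect_equal(attr(out, "n_diluents_removed"), 4)
  expect_false(any(c("DEXTROSE 5% IN WATER", "NORMAL SALINE") %in% out$medication))
  expect_true(all(out$route %in% c("IV", "oral")))
  expect_equal(cleaning_summary(out)$n_diluents_removed, 4)

  empty <- clean_records(rec[0, ], cat)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_diluents_removed"), 0)
})

test_that("medications absent from the catalog follow the configured policy", {
  cat <- tiny_catalog()
  rec <- make_records("E1", day = 1, med = "MYSTERY DRUG")
  expect_warning(clean_records(rec, cat), "absent from the catalog")
  expect_error(clean_records(rec, cat, unknown = "error"), "absent")
})

test_that("transactions collapse an episode to its distinct medication set", {
  # two patients, opposite administration order, same transaction {A, B}
  rec <- dplyr::bind_rows(
    make_records("p1", day = c(1, 2), med = c("A", "B")),
    make_records("p2", day = c(10, 21), med = c("B", "A"))
  )
  tdb <- build_transaction_db(rec)
  expect_equal(nrow(tdb), 2)
  expect_equal(tdb$items[[1]], c("A", "B"))
  expect_equal(tdb$items[[2]], c("A", "B"))

  # repeat administrations deduplicate
  rep5 <- make_records("p1", day = c(1, 2, 3, 4, 5), med = "A")
  expect_equal(build_transaction_db(rep5)$items[[1]], "A")

  # age-group partition of the database
  rec3 <- dplyr::bind_rows(
    make_records("a", 1, "A", birth = as.Date("2015-02-01")),   # 0-3m
    make_records("b", 1, "A", birth = as.Date("2015-01-20")),   # 0-3m
    make_records("c", 1, "A", birth = as.Date("2008-01-01"))    # >5y
  )
  tdb3 <- build_transaction_db(rec3)
  expect_equal(as.integer(table(tdb3$age_group)[c("0-3m", ">5y")]), c(2L, 1L))
})

test_that("sequences group same-day administrations and order days", {
  rec <- make_records(
    "p1", day = c(1, 1, 5, 8, 9), med = c("A", "B", "D", "A", "B")
  )
  sdb <- build_sequence_db(rec)
  expect_equal(sdb$days[[1]], c(1L, 5L, 8L, 9L))
  expect_equal(sdb$elements[[1]], list(c("A", "B"), "D", "A", "B"))

  one <- build_sequence_db(make_records("p1", 3, "A"))
  expect_equal(one$elements[[1]], list("A"))
  expect_equal(one$days[[1]], 3L)

  two <- build_sequence_db(make_records("p1", c(2, 2), c("B", "A")))
  expect_equal(two$elements[[1]], list(c("A", "B")))
})

test_that("utility sequences carry P(i) times the same-day dose total", {
  cat <- med_catalog(tibble::tibble(name = c("A", "Z"), utility = c(10, 0)))
  u1 <- build_utility_db(make_records("p", 1, "A", dose = 5), cat)
  expect_equal(u1$elements[[1]][[1]], c(A = 50))

  # split doses on one day aggregate before weighting
  u2 <- build_utility_db(make_records("p", c(1, 1), "A", dose = c(2, 3)), cat)
  expect_equal(u2$elements[[1]][[1]], c(A = 50))

  u0 <- build_utility_db(make_records("p", 1, "Z", dose = 100), cat)
  expect_equal(u0$elements[[1]][[1]], c(Z = 0))

  expect_error(
    build_utility_db(make_records("p", 1, "A", dose = -2), cat),
    "dose_qty"
  )
})

test_that("record counts reconcile across cleaning", {
  cat <- tiny_catalog()
  sim <- generate_emr(emr_config(n_episodes = 40, seed = 11))
  raw <- sim$records
  # corrupt two rows so the error path is exercised too
  raw$admin_date[3] <- raw$discharge_date[3] + 10
  raw$dose_qty[7] <- -5
  validated <- validate_admin_records(raw, sim$catalog)
  cleaned <- clean_records(validated, sim$catalog)
  s <- cleaning_summary(cleaned)
  expect_equal(
    nrow(raw),
    s$n_records + s$n_diluents_removed + s$n_row_errors
  )
  expect_equal(s$n_row_errors, 2)
})

test_that("flattening a sequence database reproduces the transaction database", {
  sim <- generate_emr(emr_config(n_episodes = 30, seed = 5))
  cl <- clean_records(sim$records, sim$catalog)
  tdb <- build_transaction_db(cl)
  sdb <- build_sequence_db(cl)
  expect_equal(sdb$episode_id, tdb$episode_id)
  flattened <- purrr::map(sdb$elements, ~ sort(unique(unlist(.x))))
  expect_equal(flattened, tdb$items)
})

test_that("utilities are reproducible by independent re-aggregation", {
  sim <- generate_emr(emr_config(n_episodes = 20, seed = 9))
  cl <- clean_records(sim$records, sim$catalog)
  udb <- build_utility_db(cl, sim$catalog)
  P <- stats::setNames(sim$catalog$medications$utility, sim$catalog$medications$name)
  # group-by oracle straight off the cleaned records
  oracle <- cl |>
    dplyr::mutate(day = as.integer(admin_date - admission_date) + 1L) |>
    dplyr::group_by(episode_id, day, medication) |>
    dplyr::summarise(u = sum(dose_qty) * P[medication][1], .groups = "drop")
  for (i in seq_len(nrow(udb))) {
    got <- udb$elements[[i]]
    want <- oracle[oracle$episode_id == udb$episode_id[i], ]
    for (j in seq_along(got)) {
      day <- udb$days[[i]][j]
      w <- want[want$day == day, ]
      expect_equal(got[[j]], stats::setNames(w$u, w$medication)[names(got[[j]])])
    }
  }
})

test_that("episode databases round-trip through JSON lines", {
  sim <- generate_emr(emr_config(n_episodes = 8, seed = 3))
  cl <- clean_records(sim$records, sim$catalog)
  for (db in list(build_transaction_db(cl), build_sequence_db(cl),
                  build_utility_db(cl, sim$catalog))) {
    path <- withr::local_tempfile(fileext = ".jsonl")
    write_db_jsonl(db, path)
    back <- read_db_jsonl(path)
    expect_equal(as.data.frame(back), as.data.frame(db))
    expect_equal(class(back)[1], class(db)[1])
  }
})
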