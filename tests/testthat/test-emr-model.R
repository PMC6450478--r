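test_that("age groups follow calendar-month half-open intervals", {
  expect_equal(
    as.character(assign_age_group(as.Date("2015-01-01"), as.Date("2015-02-15"))),
    "0-3m"
  )
  expect_equal(
    as.character(assign_age_group(as.Date("2010-01-01"), as.Date("2016-01-01"))),
    ">5y"
  )
  # exactly 3 months old on admission day: lower edge of the second group
  expect_equal(
    as.character(assign_age_group(as.Date("2015-01-01"), as.Date("2015-04-01"))),
    "3-6m"
  )
  # one day short of 3 months stays in the first group
  expect_equal(
    as.character(assign_age_group(as.Date("2015-01-01"), as.Date("2015-03-31"))),
    "0-3m"
  )
  expect_error(
    assign_age_group(as.Date("2015-06-01"), as.Date("2015-01-01")),
    "negative"
  )
})

test_that("every admission age in [0, 18y) lands in exactly one group", {
  withr::local_seed(42)
  admission <- as.Date("2013-06-15") + sample.int(1000, 1000, replace = TRUE)
  birth <- admission - sample.int(as.integer(18 * 365.25) - 1L, 1000, replace = TRUE)
  g <- assign_age_group(birth, admission)
  expect_false(anyNA(g))
  expect_true(all(as.character(g) %in% age_group_levels()))
  # group assignment agrees with an independent age-in-days bracketing away
  # from calendar-boundary ambiguity
  days <- as.integer(admission - birth)
  expect_true(all(as.character(g[days > 370 & days < 720]) == "1-2y"))
  expect_true(all(as.character(g[days > 61 & days < 89]) == "0-3m"))
})

test_that("reading records canonicalizes names, merges routes, collects row errors", {
  cat <- tiny_catalog()
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- make_records(
    episode = "E1", day = c(1, 1, 2), med = c("D5W", "CTX", "CEFIXIME"),
    route = c("IV drip", "IV push", "po")
  )
  write_admin_records(rec, path)
  got <- read_admin_records(path, cat)
  expect_equal(nrow(got), 3)
  expect_equal(sort(got$medication),
               sort(c("DEXTROSE 5% IN WATER", "CEFOTAXIME", "CEFIXIME")))
  expect_equal(sort(unique(got$route)), c("IV", "oral"))
  expect_equal(nrow(row_errors(got)), 0)

  # one corrupted date among 10 rows: 9 records survive, the bad line is
  # reported by its file line number
  rec10 <- make_records("E1", day = 1:10, med = paste0("M", 1:10))
  lines <- readr::format_csv(rec10)
  lines <- strsplit(lines, "\n")[[1]]
  lines[5] <- sub("2015-03-01", "not-a-date", lines[5]) # data row 4
  writeLines(lines, path)
  got <- read_admin_records(path, cat)
  expect_equal(nrow(got), 9)
  errs <- row_errors(got)
  expect_equal(nrow(errs), 1)
  expect_equal(errs$line, 5L)
  expect_match(errs$message, "date")
})

test_that("schema violations and impossible records are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(a = 1), path)
  expect_error(read_admin_records(path), "missing required column")

  bad <- make_records("E1", day = 1, med = "X")
  bad$admin_date <- bad$discharge_date + 5 # administered after discharge
  out <- validate_admin_records(bad)
  expect_equal(nrow(out), 0)
  expect_match(row_errors(out)$message, "after discharge")

  neg <- make_records("E1", day = 1, med = "X", dose = -1)
  out <- validate_admin_records(neg)
  expect_equal(nrow(out), 0)
  expect_match(row_errors(out)$message, "negative dose")
})

test_that("record collections round-trip through CSV byte-for-byte", {
  cat <- tiny_catalog()
  rec <- make_records(
    episode = rep(c("E1", "E2"), each = 3), day = c(1, 2, 3, 1, 1, 4),
    med = c("CEFOTAXIME", "CEFIXIME", "CEFOTAXIME", "ALBUTEROL",
            "BUDESONIDE", "CEFTRIAXONE"),
    dose = c(1.5, 2, 1, 0.5, 1, 2.25)
  )
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_admin_records(rec, p1)
  back <- read_admin_records(p1, cat)
  write_admin_records(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(back$medication, rec$medication)
  expect_equal(back$dose_qty, rec$dose_qty)
})

test_that("catalogs round-trip through JSON", {
  cat <- tiny_catalog()
  path <- withr::local_tempfile(fileext = ".json")
  write_med_catalog(cat, path)
  back <- read_med_catalog(path)
  expect_equal(back$medications, cat$medications[names(back$medications)])
  expect_equal(sort(names(back$synonyms)), sort(names(cat$synonyms)))
  expect_equal(back$route_merge[sort(names(back$route_merge))],
               cat$route_merge[sort(names(cat$route_merge))])
  expect_error(
    med_catalog(tibble::tibble(name = "A"), synonyms = c(x = "B")),
    "absent"
  )
  expect_error(
    med_catalog(tibble::tibble(name = c("A", "A"))),
    "unique"
  )
})
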