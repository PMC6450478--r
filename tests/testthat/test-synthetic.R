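# one moderate draw shared by the marginal-calibration checks
sim_cal <- generate_emr(emr_config(n_episodes = 1500, seed = 314))

test_that("degenerate and invalid configurations are caught", {
  empty <- generate_emr(emr_config(n_episodes = 0, seed = 1))
  expect_equal(nrow(empty$records), 0)
  expect_true(all(empty$truth$realized_count == 0))
  expect_error(emr_config(n_episodes = -1), "n_episodes")
  expect_error(
    emr_config(planted_cooccurrence = list(list(items = "A", prevalence = 1.3))),
    "prevalence"
  )
  expect_error(
    emr_config(planted_cooccurrence = list(
      list(items = c("X", "CEFOTAXIME"), prevalence = 0.1)
    )),
    "disjoint"
  )
})

test_that("a planted itemset at prevalence 1 reaches every transaction", {
  cfg <- emr_config(
    n_episodes = 40, seed = 8,
    planted_cooccurrence = list(list(items = c("P1", "P2"), prevalence = 1)),
    planted_sequences = list(), planted_high_utility = list()
  )
  sim <- generate_emr(cfg)
  cl <- clean_records(sim$records, sim$catalog)
  tdb <- build_transaction_db(cl)
  expect_true(all(purrr::map_lgl(tdb$items, ~ all(c("P1", "P2") %in% .x))))
  expect_equal(sim$truth$realized_count, 40L)
})

test_that("realized planted prevalence stays inside exact binomial bounds", {
  cfg <- emr_config(
    n_episodes = 500, seed = 21,
    planted_cooccurrence = list(list(items = c("P1", "P2"), prevalence = 0.3)),
    planted_sequences = list(), planted_high_utility = list()
  )
  sim <- generate_emr(cfg)
  ci <- stats::qbinom(c(0.005, 0.995), 500, 0.3)
  expect_gte(sim$truth$realized_count, ci[1])
  expect_lte(sim$truth$realized_count, ci[2])
})

test_that("default marginals track the study-like calibration targets", {
  cl <- clean_records(sim_cal$records, sim_cal$catalog)
  episodes <- dplyr::distinct(cl, episode_id, birth_date, admission_date,
                              discharge_date, patient_sex)
  g <- assign_age_group(episodes$birth_date, episodes$admission_date)
  # under-5 share near 86.6%
  under5 <- mean(g != ">5y")
  expect_lt(abs(under5 - 0.8655), 0.03)
  # every episode in exactly one group
  expect_false(anyNA(g))
  # 9-15 day stays near 60%
  stay <- as.integer(episodes$discharge_date - episodes$admission_date) + 1L
  expect_lt(abs(mean(stay >= 9 & stay <= 15) - 0.601), 0.04)
  expect_true(all(stay >= 1 & stay <= 30))
  # male share near 60.4%
  expect_lt(abs(mean(episodes$patient_sex == "male") - 0.6037), 0.04)
  # long-tailed catalog: top-40 coverage in a band around 0.74
  ft <- frequency_table(cl, top_n = 40)
  expect_gt(ft$top_coverage, 0.60)
  expect_lt(ft$top_coverage, 0.85)
  # IV-heavy routes
  expect_gt(route_share(cl, "IV")$share, 0.25)
})

test_that("diluents are generated alongside IV therapy and removed by cleaning", {
  raw <- sim_cal$records
  dil_short <- c("D5W", "NS")
  expect_gt(sum(raw$medication %in% dil_short), 0)
  cl <- clean_records(raw, sim_cal$catalog)
  expect_equal(
    sum(is_removed <- canonicalize_medication(raw$medication, sim_cal$catalog) %in%
          c("DEXTROSE 5% IN WATER", "NORMAL SALINE")),
    attr(cl, "n_diluents_removed")
  )
})

test_that("the truth ledger counts exactly match mined planted support", {
  sim <- generate_emr(emr_config(n_episodes = 250, seed = 55))
  cl <- clean_records(sim$records, sim$catalog)
  tdb <- build_transaction_db(cl)
  sdb <- build_sequence_db(cl)
  udb <- build_utility_db(cl, sim$catalog)
  for (i in seq_len(nrow(sim$truth))) {
    row <- sim$truth[i, ]
    if (row$kind == "cooccurrence") {
      set <- row$elements[[1]][[1]]
      mined <- sum(purrr::map_lgl(tdb$items, ~ all(set %in% .x)))
    } else if (row$kind == "sequence") {
      mined <- sum(purrr::map_lgl(sdb$elements, ~ seq_contains(.x, row$elements[[1]])))
    } else {
      pu <- pattern_utility(udb, row$elements[[1]])
      mined <- pu$support_count
      expect_equal(pu$utility, row$utility)
    }
    expect_equal(mined, row$realized_count,
                 info = paste("pattern", row$pattern))
  }
})

test_that("generation is byte-deterministic and leaves the RNG state alone", {
  cfg <- emr_config(n_episodes = 60, seed = 77)
  set.seed(1); before <- stats::runif(1)
  set.seed(1)
  s1 <- generate_emr(cfg)
  after <- stats::runif(1)
  expect_equal(before, after) # caller RNG untouched
  s2 <- generate_emr(cfg)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_admin_records(s1$records, p1)
  write_admin_records(s2$records, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(s1$truth$episodes, s2$truth$episodes)
})

test_that("synthetic datasets round-trip through the on-disk layout", {
  sim <- generate_emr(emr_config(n_episodes = 10, seed = 4))
  dir <- withr::local_tempdir()
  write_emr_dataset(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("records.csv", "catalog.json", "truth.json")))))
  back <- read_admin_records(file.path(dir, "records.csv"),
                             read_med_catalog(file.path(dir, "catalog.json")))
  expect_equal(nrow(back), nrow(sim$records))
  expect_equal(nrow(row_errors(back)), 0)
})
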