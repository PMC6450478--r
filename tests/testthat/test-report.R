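test_that("top-k ranking is stable with documented tie-breaks", {
  tdb <- as_tdb(list(c("A", "B"), c("A", "C"), c("B", "C")))
  res <- mine_frequent_itemsets(tdb, 0.3)
  top <- top_k_patterns(res, k = 10)
  expect_lte(nrow(top), 10)
  expect_equal(nrow(top_k_patterns(res, k = 2)), 2)
  # ties on score resolve lexicographically on the rendering
  pairs <- top[top$support_count == 2 & lengths(top$items) == 2, ]
  expect_equal(pairs$pattern, sort(pairs$pattern))
  expect_error(top_k_patterns(res, k = 0), "k must be")

  # agreement with a plain full-sort oracle on random scores
  withr::local_seed(31)
  for (i in 1:20) {
    fake <- res
    fake$support <- sample(c(0.3, 0.6, 0.9), nrow(res), replace = TRUE)
    got <- top_k_patterns(fake, k = 4)
    oracle <- fake[order(-fake$support, -fake$support_count, fake$pattern), ]
    expect_equal(got$pattern, utils::head(oracle$pattern, 4))
  }
})

test_that("route shares report numerator, denominator and partition to 1", {
  rec <- make_records("E1", day = 1:10, med = paste0("M", 1:10),
                      route = c(rep("IV", 4), rep("oral", 3),
                                rep("inhalation", 2), "topical"))
  iv <- route_share(rec, "IV")
  expect_equal(iv$share, 0.4)
  expect_equal(iv$numerator, 4)
  expect_equal(iv$denominator, 10)
  expect_equal(route_share(rec, unique(rec$route))$share, 1)
  all_routes <- c("IV", "oral", "inhalation", "topical")
  expect_equal(sum(purrr::map_dbl(all_routes, ~ route_share(rec, .x)$share)), 1)
  expect_error(route_share(rec[0, ], "IV"), "empty")
})

test_that("frequency tables give per-stratum proportions and top-n coverage", {
  # uniform catalog of 5 medications
  rec <- make_records("E1", day = 1:5, med = paste0("M", 1:5))
  ft <- frequency_table(rec, top_n = 5)
  expect_true(all(ft$overall$prop == 0.2))

  # 40 records where the top two medications cover 30
  rec2 <- make_records("E1", day = rep(1:40),
                       med = c(rep("A", 18), rep("B", 12), paste0("X", 1:10)))
  ft2 <- frequency_table(rec2, top_n = 2)
  expect_equal(ft2$top_coverage, 0.75)
  expect_equal(ft2$top_medications, c("A", "B"))

  # stratified counts sum to the global counts
  sim <- generate_emr(emr_config(n_episodes = 25, seed = 2))
  cl <- clean_records(sim$records, sim$catalog)
  ft3 <- frequency_table(cl, by = "age_group")
  sums <- ft3$by_stratum |>
    dplyr::count(medication, wt = n, name = "n_total") |>
    dplyr::arrange(medication)
  ov <- dplyr::arrange(ft3$overall[, c("medication", "n")], medication)
  expect_equal(sums$medication, ov$medication)
  expect_equal(sums$n_total, ov$n)
  ft4 <- frequency_table(cl, by = "calendar_year")
  expect_equal(sum(ft4$by_stratum$n), nrow(cl))
})

test_that("Fleiss kappa matches hand computation and behaves at the extremes", {
  # perfect agreement
  expect_equal(fleiss_kappa(rbind(c(4, 0), c(0, 4), c(4, 0)))$kappa, 1)

  # hand-worked example: 4 subjects, 3 raters, 2 categories
  # counts: (3,0) (2,1) (1,2) (0,3)
  # P_i = 1, 1/3, 1/3, 1; Pbar = 2/3
  # p = (6/12, 6/12); Pe = 1/2; kappa = (2/3 - 1/2)/(1 - 1/2) = 1/3
  tab <- rbind(c(3, 0), c(2, 1), c(1, 2), c(0, 3))
  expect_equal(fleiss_kappa(tab)$kappa, 1 / 3, tolerance = 1e-12)

  # random ratings from two categories: kappa near zero
  withr::local_seed(99)
  counts <- stats::rbinom(4000, size = 6, prob = 0.5)
  big <- cbind(counts, 6 - counts)
  expect_lt(abs(fleiss_kappa(big)$kappa), 0.02)

  # invariant to subject order and category relabeling
  perm <- sample.int(nrow(tab))
  expect_equal(fleiss_kappa(tab[perm, ])$kappa, fleiss_kappa(tab)$kappa)
  expect_equal(fleiss_kappa(tab[, c(2, 1)])$kappa, fleiss_kappa(tab)$kappa)

  expect_error(fleiss_kappa(rbind(c(3, 0), c(3, 0))), "kappa undefined")
  expect_error(fleiss_kappa(rbind(c(3, 0))), "2 subjects")
  expect_error(fleiss_kappa(rbind(c(3, 0), c(2, 1), c(3, 1))), "same number")
})

test_that("rating tables read from CSV feed the kappa computation", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,valid,invalid",
    "pattern1,3,0",
    "pattern2,2,1",
    "pattern3,1,2",
    "pattern4,0,3"
  ), path)
  tab <- read_rating_table(path)
  expect_equal(fleiss_kappa(tab)$kappa, 1 / 3, tolerance = 1e-12)
})

test_that("cross-algorithm comparison aligns identical combinations", {
  tdb <- as_tdb(
    list(c("A", "B"), c("A", "B"), c("C", "D"), c("C", "D")),
    groups = c("0-3m", "0-3m", ">5y", ">5y")
  )
  sdb <- as_sdb(
    list(list("A", "B"), list(c("A", "B")), list("C"), list("D")),
    groups = c("0-3m", "0-3m", ">5y", ">5y")
  )
  fp <- mine_frequent_itemsets(tdb, 0.5, by_age_group = TRUE)
  ps <- mine_sequential_patterns(sdb, 0.5, by_age_group = TRUE)
  rep <- build_comparison(list(fpgrowth = fp, prefixspan = ps), k = 10)

  combos <- rep$combinations
  # the flattened sequence <A, B> and the itemset (A, B) share one row
  ab <- combos[combos$combination == "A, B", ]
  expect_equal(nrow(ab), 1)
  expect_true(ab$fpgrowth && ab$prefixspan)
  expect_true(ab$`0-3m`)
  expect_false(ab$`>5y`)
  # (C, D) was frequent as an itemset but never as a sequence
  cd <- combos[combos$combination == "C, D", ]
  expect_true(cd$fpgrowth)
  expect_false(cd$prefixspan)
  expect_lte(rep$n_combinations, 2 * 6 * 10)
  expect_error(build_comparison(list(fp, fp)), "uniquely named")

  # tidy/glance/plot surfaces
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(glance(rep)$n_combinations, rep$n_combinations)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(autoplot(fp), "ggplot")
  expect_equal(glance(fp)$algorithm, "fpgrowth")
})

test_that("pattern and report writers emit readable TSV/JSON", {
  tdb <- as_tdb(list(c("A", "B"), c("A", "B")))
  fp <- mine_frequent_itemsets(tdb, 0.5)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_patterns_tsv(fp, p1)
  back <- readr::read_tsv(p1, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(fp))
  expect_true(all(c("pattern", "support_count", "support") %in% names(back)))
})
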