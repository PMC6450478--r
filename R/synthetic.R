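#' Synthetic EMR generator configuration
#'
#' Describes a synthetic inpatient medication-administration dataset with
#' the statistical structure the pipeline assumes: six admission-age strata
#' with realistic paediatric-pneumonia proportions, hospital stays
#' concentrated on 9–15 days, a long-tailed (Zipf-like) medication catalog
#' whose top 40 items cover roughly three quarters of records, IV-heavy
#' routes with diluents co-administered alongside IV medications, and
#' planted ground-truth patterns: same-day co-occurrence itemsets,
#' day-gapped sequential patterns, and a low-frequency/high-dose
#' high-utility pattern.
#'
#' The defaults emulate a large paediatric-pneumonia inpatient cohort:
#' age weights proportional to (0.3753, 0.0799, 0.1015, 0.1087, 0.2000,
#' 0.1345) across the six groups (86.6% under five), 60.1% of stays lasting
#' 9–15 days, 60.4% male, a 650-item catalog with Zipf exponent 1.17
#' (top-40 record coverage about 0.74), and planted-pattern day gaps
#' averaging 5–7 days.
#'
#' @param n_episodes Number of hospitalization episodes.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @param age_group_weights Named numeric of length 6 (normalized
#'   internally).
#' @param male_prob Probability an episode's patient is male.
#' @param stay_9_15_mass Probability mass placed uniformly on stays of 9–15
#'   days; the rest spreads over 2–8 and 16–30 days with decaying weights.
#' @param catalog_size Number of background medications.
#' @param zipf_s Zipf exponent of the background frequency weights.
#' @param meds_per_day_lambda Background distinct-medication draws per day
#'   are `1 + Poisson(lambda)`.
#' @param route_weights Named probabilities (IV, oral, inhalation, topical)
#'   with which each background medication is assigned its route.
#' @param diluent_attach_prob Probability that an IV administration is
#'   accompanied by a same-day diluent record (D5W or NS).
#' @param planted_cooccurrence List of `list(items =, prevalence =)`
#'   same-day itemsets.
#' @param planted_sequences List of
#'   `list(first =, second =, prevalence =, gap_mean =)` two-step patterns;
#'   the day gap is `1 + Geometric(1 / gap_mean)`, clipped to the stay.
#' @param planted_high_utility List of
#'   `list(items =, prevalence =, dose_multiplier =)` same-day high-dose
#'   patterns.
#' @return An object of class `emr_config`.
#' @export
emr_config <- function(n_episodes = 2000L,
                       seed = 20100101L,
                       age_group_weights = c(
                         "0-3m" = 0.3753, "3-6m" = 0.0799, "6-12m" = 0.1015,
                         "1-2y" = 0.1087, "2-5y" = 0.2000, ">5y" = 0.1345
                       ),
                       male_prob = 0.6037,
                       stay_9_15_mass = 0.601,
                       catalog_size = 650L,
                       zipf_s = 1.17,
                       meds_per_day_lambda = 2,
                       route_weights = c(
                         IV = 0.45, oral = 0.28, inhalation = 0.12,
                         topical = 0.15
                       ),
                       diluent_attach_prob = 0.9,
                       planted_cooccurrence = list(
                         list(items = c("CEFTRIAXONE", "AZITHROMYCIN"),
                              prevalence = 0.30),
                         list(items = c("ALBUTEROL", "BUDESONIDE",
                                        "IPRATROPIUM BROMIDE"),
                              prevalence = 0.25)
                       ),
                       planted_sequences = list(
                         list(first = "CEFOTAXIME", second = "CEFIXIME",
                              prevalence = 0.30, gap_mean = 7),
                         list(first = "AMPICILLIN", second = "CEFUROXIME",
                              prevalence = 0.25, gap_mean = 5)
                       ),
                       planted_high_utility = list(
                         list(items = c("FAT EMULSION", "VITAMIN K1"),
                              prevalence = 0.05, dose_multiplier = 25)
                       )) {
  if (n_episodes < 0) abort("n_episodes must be >= 0")
  if (length(age_group_weights) != 6 || any(age_group_weights < 0)) {
    abort("age_group_weights must be 6 non-negative numbers")
  }
  names(age_group_weights) <- age_group_levels()
  prevs <- c(
    purrr::map_dbl(planted_cooccurrence, "prevalence"),
    purrr::map_dbl(planted_sequences, "prevalence"),
    purrr::map_dbl(planted_high_utility, "prevalence")
  )
  if (any(prevs < 0 | prevs > 1)) abort("prevalences must be in [0, 1]")
  cfg <- structure(
    list(
      n_episodes = as.integer(n_episodes), seed = as.integer(seed),
      age_group_weights = age_group_weights / sum(age_group_weights),
      male_prob = male_prob, stay_9_15_mass = stay_9_15_mass,
      catalog_size = as.integer(catalog_size), zipf_s = zipf_s,
      meds_per_day_lambda = meds_per_day_lambda,
      route_weights = route_weights / sum(route_weights),
      diluent_attach_prob = diluent_attach_prob,
      planted_cooccurrence = planted_cooccurrence,
      planted_sequences = planted_sequences,
      planted_high_utility = planted_high_utility
    ),
    class = "emr_config"
  )
  planted_med_table(cfg) # validates planted-name disjointness
  cfg
}

#' @export
print.emr_config <- function(x, ...) {
  cat("<emr_config> ", x$n_episodes, " episodes, ", x$catalog_size,
      " background medications, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# evaluate `code` under a fixed RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# calendar-month shift with day-of-month clamping
add_months <- function(date, m) {
  lt <- as.POSIXlt(date)
  tot <- lt$year * 12L + lt$mon + m
  y <- tot %/% 12L
  mon <- tot %% 12L
  dim <- days_in_month(y + 1900L, mon + 1L)
  as.Date(sprintf("%04d-%02d-%02d", y + 1900L, mon + 1L, pmin(lt$mday, dim)))
}

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  d[month == 2 & leap] <- 29L
  d
}

planted_med_table <- function(config) {
  meds <- c(
    unlist(purrr::map(config$planted_cooccurrence, "items")),
    unlist(purrr::map(config$planted_sequences, ~ c(.x$first, .x$second))),
    unlist(purrr::map(config$planted_high_utility, "items"))
  )
  kinds <- c(
    rep("cooccurrence", length(unlist(purrr::map(config$planted_cooccurrence, "items")))),
    rep("sequence", length(unlist(purrr::map(config$planted_sequences, ~ c(.x$first, .x$second))))),
    rep("high_utility", length(unlist(purrr::map(config$planted_high_utility, "items"))))
  )
  if (anyDuplicated(meds)) {
    abort("planted patterns must use disjoint medication names")
  }
  tibble(name = meds, kind = kinds)
}

#' Build the synthetic medication catalog for a generator config
#'
#' Background medications (`MED0001`, ...) get integer utility values
#' `P` in 1–10, a route drawn from `route_weights` and a drug class;
#' planted medications get fixed utilities (`P = 5`, high-utility items
#' `P = 8`); the two diluents (dextrose 5% in water and normal saline,
#' `P = 0`, IV) carry the synonyms `D5W` and `NS`, and the route-merge map
#' collapses raw labels such as `"IV drip"` to the four merged routes.
#'
#' @param config An [emr_config()].
#' @return A [med_catalog()] whose `medications` tibble also carries the
#'   generator's `route` annotation.
#' @export
synthetic_catalog <- function(config) {
  with_seed(config$seed + 1L, {
    n <- config$catalog_size
    bg <- tibble(
      name = sprintf("MED%04d", seq_len(n)),
      utility = as.numeric(sample(1:10, n, replace = TRUE)),
      is_diluent = FALSE,
      class = sample(
        c("antibiotic", "antiasthmatic", "expectorant", "corticosteroid",
          "nutritional supplement", "probiotic", "antiseptic", "other"),
        n, replace = TRUE,
        prob = c(0.12, 0.06, 0.06, 0.05, 0.08, 0.04, 0.04, 0.55)
      ),
      route = sample(names(config$route_weights), n, replace = TRUE,
                     prob = config$route_weights)
    )
    planted <- planted_med_table(config)
    pl <- tibble(
      name = planted$name,
      utility = ifelse(planted$kind == "high_utility", 8, 5),
      is_diluent = FALSE,
      class = dplyr::recode(planted$kind,
        cooccurrence = "antibiotic", sequence = "antibiotic",
        high_utility = "nutritional supplement"
      ),
      route = ifelse(planted$kind == "high_utility", "IV",
                     ifelse(planted$name %in% c("ALBUTEROL", "BUDESONIDE",
                                                "IPRATROPIUM BROMIDE"),
                            "inhalation", "IV"))
    )
    dil <- tibble(
      name = c("DEXTROSE 5% IN WATER", "NORMAL SALINE"),
      utility = 0, is_diluent = TRUE, class = "diluent", route = "IV"
    )
    med_catalog(
      bind_rows(bg, pl, dil),
      synonyms = c(
        "D5W" = "DEXTROSE 5% IN WATER",
        "NS" = "NORMAL SALINE"
      ),
      route_merge = c(
        "IV drip" = "IV", "IV push" = "IV", "intravenous" = "IV",
        "po" = "oral", "by mouth" = "oral",
        "neb" = "inhalation", "nebulization" = "inhalation",
        "external" = "topical"
      )
    )
  })
}

raw_route_label <- function(route) {
  # raw labels later collapsed by the catalog's route-merge map
  pool <- switch(route,
    IV = c("IV", "IV drip", "IV push", "intravenous"),
    oral = c("oral", "po", "by mouth"),
    inhalation = c("inhalation", "neb", "nebulization"),
    topical = c("topical", "external")
  )
  pool[sample.int(length(pool), 1L)]
}

sample_stay <- function(config) {
  if (runif(1) < config$stay_9_15_mass) {
    sample(9:15, 1L)
  } else {
    days <- c(2:8, 16:30)
    w <- c(seq(1, 4, length.out = 7), exp(-0.18 * (16:30 - 15)) * 4)
    days[sample.int(length(days), 1L, prob = w)]
  }
}

sample_age_dates <- function(group, admission) {
  bounds <- list(
    "0-3m" = c(0L, 3L), "3-6m" = c(3L, 6L), "6-12m" = c(6L, 12L),
    "1-2y" = c(12L, 24L), "2-5y" = c(24L, 60L), ">5y" = c(60L, 216L)
  )[[group]]
  m <- sample(seq(bounds[1], bounds[2] - 1L), 1L)
  d <- sample(0:27, 1L)
  add_months(admission, -m) - d
}

#' Generate a synthetic EMR dataset
#'
#' Draws a full medication-administration table (including diluent records
#' and raw, un-merged route labels, so the cleaning step has real work to
#' do) plus a machine-readable truth ledger of every planted pattern with
#' its realized episode count and — for high-utility patterns — realized
#' total utility. Generation is fully deterministic given `config` and
#' leaves the caller's RNG state untouched.
#'
#' @param config An [emr_config()].
#' @return A list of class `emr_dataset`: `records` (the raw administration
#'   tibble), `catalog` (the matching [med_catalog()]) and `truth` (tibble:
#'   `pattern_id`, `kind`, `pattern`, `elements`, `configured_prevalence`,
#'   `realized_count`, `realized_prevalence`, `utility`, list-column
#'   `episodes`).
#' @export
generate_emr <- function(config) {
  catalog <- synthetic_catalog(config)
  meds <- catalog$medications
  bg_names <- meds$name[grepl("^MED", meds$name)]
  bg_routes <- setNames(meds$route[match(bg_names, meds$name)], bg_names)
  zipf_w <- seq_along(bg_names)^-config$zipf_s
  med_route <- setNames(meds$route, meds$name)
  med_P <- setNames(meds$utility, meds$name)

  n <- config$n_episodes
  truth_hits <- purrr::map(
    seq_len(length(config$planted_cooccurrence) +
              length(config$planted_sequences) +
              length(config$planted_high_utility)),
    ~ character(0)
  )
  truth_util <- numeric(length(truth_hits))

  rows <- if (n == 0) list() else with_seed(config$seed, {
    purrr::map(seq_len(n), function(i) {
      eid <- sprintf("E%05d", i)
      g <- sample(age_group_levels(), 1L, prob = config$age_group_weights)
      admission <- as.Date("2010-01-01") +
        sample.int(as.integer(as.Date("2015-12-31") - as.Date("2010-01-01")) + 1L, 1L) - 1L
      L <- sample_stay(config)
      discharge <- admission + (L - 1L)
      birth <- sample_age_dates(g, admission)
      sex <- if (runif(1) < config$male_prob) "male" else "female"

      med <- character(0); day <- integer(0); dose <- numeric(0)
      for (d in seq_len(L)) {
        k <- 1L + stats::rpois(1L, config$meds_per_day_lambda)
        k <- min(k, length(bg_names))
        picks <- sample(bg_names, k, prob = zipf_w)
        med <- c(med, picks)
        day <- c(day, rep(d, k))
        dose <- c(dose, round(rgamma(k, shape = 4, scale = 0.5), 2))
      }

      pid <- 0L
      for (p in config$planted_cooccurrence) {
        pid <- pid + 1L
        if (runif(1) < p$prevalence) {
          d0 <- sample.int(L, 1L)
          med <- c(med, p$items)
          day <- c(day, rep(d0, length(p$items)))
          dose <- c(dose, round(rgamma(length(p$items), shape = 4, scale = 0.5), 2))
          truth_hits[[pid]] <<- c(truth_hits[[pid]], eid)
        }
      }
      for (p in config$planted_sequences) {
        pid <- pid + 1L
        if (runif(1) < p$prevalence && L >= 2) {
          d1 <- sample.int(min(3L, L - 1L), 1L)
          gap <- 1L + stats::rgeom(1L, 1 / p$gap_mean)
          d2 <- min(d1 + gap, L)
          med <- c(med, p$first, p$second)
          day <- c(day, d1, d2)
          dose <- c(dose, round(rgamma(2, shape = 4, scale = 0.5), 2))
          truth_hits[[pid]] <<- c(truth_hits[[pid]], eid)
        }
      }
      for (p in config$planted_high_utility) {
        pid <- pid + 1L
        if (runif(1) < p$prevalence) {
          d0 <- sample.int(L, 1L)
          q <- round(rgamma(length(p$items), shape = 4, scale = 0.5), 2) *
            p$dose_multiplier
          med <- c(med, p$items)
          day <- c(day, rep(d0, length(p$items)))
          dose <- c(dose, q)
          truth_hits[[pid]] <<- c(truth_hits[[pid]], eid)
          truth_util[pid] <<- truth_util[pid] + sum(med_P[p$items] * q)
        }
      }

      # diluent carriers alongside IV administrations (short raw names,
      # exercising synonym canonicalization during reading/cleaning)
      iv <- which(med_route[med] == "IV")
      iv_d <- day[iv][runif(length(iv)) < config$diluent_attach_prob]
      if (length(iv_d)) {
        med <- c(med, sample(c("D5W", "NS"), length(iv_d), replace = TRUE))
        day <- c(day, iv_d)
        dose <- c(dose, rep(100, length(iv_d)))
      }

      route_raw <- purrr::map_chr(med_route[canonicalize_medication(med, catalog)],
                                  raw_route_label)
      tibble(
        episode_id = eid, patient_sex = sex, birth_date = birth,
        admission_date = admission, discharge_date = discharge,
        medication = med, route = route_raw,
        dose_qty = dose,
        dose_unit = ifelse(med %in% c("D5W", "NS"), "ml", "mg"),
        admin_date = admission + (day - 1L)
      )
    })
  })

  records <- bind_rows(rows)
  if (nrow(records)) {
    records <- arrange(records, .data$episode_id, .data$admin_date,
                       .data$medication)
  } else {
    records <- tibble(
      episode_id = character(), patient_sex = character(),
      birth_date = as.Date(character()), admission_date = as.Date(character()),
      discharge_date = as.Date(character()), medication = character(),
      route = character(), dose_qty = numeric(), dose_unit = character(),
      admin_date = as.Date(character())
    )
  }

  truth <- synthetic_truth(config, truth_hits, truth_util, n)
  structure(list(records = records, catalog = catalog, truth = truth),
            class = "emr_dataset")
}

synthetic_truth <- function(config, hits, util, n) {
  entries <- list()
  pid <- 0L
  for (p in config$planted_cooccurrence) {
    pid <- pid + 1L
    entries[[pid]] <- tibble(
      kind = "cooccurrence",
      pattern = render_itemset(sort(p$items)),
      elements = list(list(sort(p$items))),
      configured_prevalence = p$prevalence,
      utility = NA_real_,
      episodes = list(hits[[pid]])
    )
  }
  for (p in config$planted_sequences) {
    pid <- pid + 1L
    entries[[pid]] <- tibble(
      kind = "sequence",
      pattern = render_sequence(list(p$first, p$second)),
      elements = list(list(p$first, p$second)),
      configured_prevalence = p$prevalence,
      utility = NA_real_,
      episodes = list(hits[[pid]])
    )
  }
  for (p in config$planted_high_utility) {
    pid <- pid + 1L
    entries[[pid]] <- tibble(
      kind = "high_utility",
      pattern = render_sequence(list(sort(p$items))),
      elements = list(list(sort(p$items))),
      configured_prevalence = p$prevalence,
      utility = util[pid],
      episodes = list(hits[[pid]])
    )
  }
  out <- bind_rows(entries)
  if (!nrow(out)) {
    return(tibble(
      pattern_id = integer(), kind = character(), pattern = character(),
      elements = list(), configured_prevalence = double(),
      realized_count = integer(), realized_prevalence = double(),
      utility = double(), episodes = list()
    ))
  }
  out$pattern_id <- seq_len(nrow(out))
  out$realized_count <- lengths(out$episodes)
  out$realized_prevalence <- if (n > 0) out$realized_count / n else NA_real_
  out[c("pattern_id", "kind", "pattern", "elements", "configured_prevalence",
        "realized_count", "realized_prevalence", "utility", "episodes")]
}

#' @export
print.emr_dataset <- function(x, ...) {
  cat("<emr_dataset> ", nrow(x$records), " administration records, ",
      dplyr::n_distinct(x$records$episode_id), " episodes, ",
      nrow(x$truth), " planted patterns\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits `records.csv` (the administration-record schema), `catalog.json`
#' and `truth.json` into `dir`. Output is byte-deterministic for a fixed
#' config.
#'
#' @param dataset An `emr_dataset` from [generate_emr()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_emr_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_admin_records(dataset$records, file.path(dir, "records.csv"))
  write_med_catalog(dataset$catalog, file.path(dir, "catalog.json"))
  truth <- dataset$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
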