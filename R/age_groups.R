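#' Paediatric age groups
#'
#' The six admission-age strata used throughout the package:
#' `0-3m`, `3-6m`, `6-12m`, `1-2y`, `2-5y`, `>5y`. Boundaries use
#' calendar-month arithmetic with half-open intervals
#' (\[0,3m), \[3m,6m), \[6m,12m), \[1y,2y), \[2y,5y), \[5y,18y)), so the six
#' groups partition the paediatric age range and every episode belongs to
#' exactly one group.
#'
#' @return Character vector of the six group labels, in age order.
#' @export
age_group_levels <- function() {
  c("0-3m", "3-6m", "6-12m", "1-2y", "2-5y", ">5y")
}

# Whole calendar months elapsed from `from` to `to` (both Date).
# A month is complete when the day-of-month of `to` has reached that of
# `from`; this is the everyday "age in months" convention.
months_between <- function(from, to) {
  from <- as.POSIXlt(from)
  to <- as.POSIXlt(to)
  m <- 12L * (to$year - from$year) + (to$mon - from$mon)
  m - as.integer(to$mday < from$mday)
}

#' Assign an admission-age group
#'
#' Age is computed as the calendar difference between the admission date and
#' the birth date, and mapped to one of the six half-open strata returned by
#' [age_group_levels()].
#'
#' @param birth_date,admission_date `Date` vectors (recycled to a common
#'   length). `birth_date` must not be after `admission_date`.
#' @return A factor with levels `age_group_levels()`.
#' @examples
#' assign_age_group(as.Date("2015-01-01"), as.Date("2015-02-15")) # 0-3m
#' assign_age_group(as.Date("2010-01-01"), as.Date("2016-01-01")) # >5y
#' @export
assign_age_group <- function(birth_date, admission_date) {
  birth_date <- as.Date(birth_date)
  admission_date <- as.Date(admission_date)
  if (any(is.na(birth_date)) || any(is.na(admission_date))) {
    abort("dates must not be NA")
  }
  n <- max(length(birth_date), length(admission_date))
  birth_date <- rep_len(birth_date, n)
  admission_date <- rep_len(admission_date, n)
  if (any(birth_date > admission_date)) {
    abort("birth_date must be on or before admission_date (negative age)")
  }
  m <- months_between(birth_date, admission_date)
  lab <- dplyr::case_when(
    m < 3 ~ "0-3m",
    m < 6 ~ "3-6m",
    m < 12 ~ "6-12m",
    m < 24 ~ "1-2y",
    m < 60 ~ "2-5y",
    TRUE ~ ">5y"
  )
  factor(lab, levels = age_group_levels())
}
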