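# Six-month analysis periods. The first semester of each calendar year
# (January-June) is the breeding season.

#' Semester label of a date
#'
#' @param dates `Date` vector (or coercible).
#' @return character labels like `"2014S1"`.
#' @export
semester_of <- function(dates) {
  dates <- as.Date(dates)
  y <- as.integer(format(dates, "%Y"))
  m <- as.integer(format(dates, "%m"))
  paste0(y, "S", ifelse(m <= 6, 1L, 2L))
}

#' Is a semester the breeding season?
#'
#' @param semester character labels like `"2014S1"`.
#' @return integer vector: 1 for first (breeding) semesters, 0 otherwise.
#' @export
semester_breeding <- function(semester) {
  as.integer(substr(semester, 6, 6) == "1")
}

#' Year of a semester label
#' @param semester character labels like `"2014S1"`.
#' @return integer years.
#' @export
semester_year <- function(semester) as.integer(substr(semester, 1, 4))

#' Calendar months of a semester
#' @param semester a single semester label.
#' @return character vector of `"YYYY-MM"` months.
#' @export
semester_months <- function(semester) {
  y <- semester_year(semester)
  m <- if (substr(semester, 6, 6) == "1") 1:6 else 7:12
  sprintf("%d-%02d", y, m)
}

#' Calendar dates of a semester
#' @param semester a single semester label.
#' @return `Date` vector covering the whole semester.
#' @export
semester_dates <- function(semester) {
  y <- semester_year(semester)
  if (substr(semester, 6, 6) == "1")
    seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-06-30", y)), by = "day")
  else
    seq(as.Date(sprintf("%d-07-01", y)), as.Date(sprintf("%d-12-31", y)), by = "day")
}

#' Consecutive semester labels
#' @param first first semester label (e.g. `"2013S2"`).
#' @param n number of semesters.
#' @return character vector of `n` consecutive labels.
#' @export
semester_seq <- function(first, n) {
  y <- semester_year(first)
  h <- as.integer(substr(first, 6, 6))
  idx <- (y * 2 + (h - 1)) + seq_len(n) - 1L
  paste0(idx %/% 2, "S", idx %% 2 + 1L)
}
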