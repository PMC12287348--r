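#' Construct a 2x2 contingency table for disproportionality statistics
#'
#' @param a reports with the medication and the side effect.
#' @param b reports with the medication, without the side effect.
#' @param c reports with the side effect, without the medication.
#' @param d reports with neither.
#' @return an object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    stop("contingency cells must be non-negative integers")
  }
  structure(as.list(x), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("med", "no med"), c("effect", "no effect")))
  print(m)
  invisible(x)
}

#' Retain single-medication reports
#'
#' Drops every report that carries more than one medication; reports are
#' never modified, only removed. Emits a warning (not an error) when nothing
#' survives.
#'
#' @param db a report `data.table` (`report_id`, `medication_id`, `term_id`,
#'   `term_role`).
#' @return the filtered `data.table`.
#' @export
filter_single_med_reports <- function(db) {
  if (nrow(db) == 0L) stop("report database is empty")
  medication_id <- report_id <- NULL
  per_report <- db[, list(n_meds = data.table::uniqueN(medication_id)),
                   by = report_id]
  keep <- per_report$report_id[per_report$n_meds == 1L]
  out <- db[db$report_id %in% keep]
  if (nrow(out) == 0L) {
    warning("no single-medication reports remain after filtering")
  }
  out
}

#' Build the 2x2 table for one medication-term pair
#'
#' Cell `a` counts reports with both the medication and the term, `b` the
#' medication without the term, `c` the term without the medication, `d` the
#' remainder; the four cells always sum to the number of reports. A medication
#' or term absent from the database yields a zero margin rather than an error.
#'
#' @param db a report `data.table`, already filtered to single-medication
#'   reports.
#' @param medication_id,term_id identifiers of the pair.
#' @return a [contingency_2x2()].
#' @export
build_pair_table <- function(db, medication_id, term_id) {
  se <- unique(db[db$term_role == "side_effect",
                  c("report_id", "medication_id", "term_id")])
  reports <- unique(db$report_id)
  n <- length(reports)
  med_reports <- unique(se$report_id[se$medication_id == medication_id])
  term_reports <- unique(se$report_id[se$term_id == term_id])
  a <- length(intersect(med_reports, term_reports))
  b <- length(med_reports) - a
  c_ <- length(term_reports) - a
  contingency_2x2(a, b, c_, n - a - b - c_)
}

#' Proportional reporting ratio
#'
#' PRR = \[a/(a+b)\] / \[c/(c+d)\]: the side-effect rate among the
#' medication's reports over the rate among all other reports. Returns `Inf`
#' when the comparator rate is zero but the effect was observed with the
#' medication (`c = 0`, `a > 0`) and `0` when `a = 0` with `c > 0`.
#'
#' @param table a [contingency_2x2()].
#' @return a non-negative number, possibly `Inf`.
#' @export
prr <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  if (a + b == 0) stop("undefined PRR: no reports with the medication")
  if (c_ + d == 0) stop("undefined PRR: empty comparator")
  if (a == 0 && c_ == 0) return(NaN)
  if (c_ == 0) return(Inf)
  if (a == 0) return(0)
  (a * (c_ + d)) / ((a + b) * c_) # exact on integer-valued cells
}

#' Yates' continuity-corrected chi-square statistic for a 2x2 table
#'
#' Computed by the margin formula
#' `N * (max(0, |ad - bc| - N/2))^2 / ((a+b)(c+d)(a+c)(b+d))`. The correction
#' is clamped at zero so tiny tables are never over-corrected. The statistic
#' is undefined (error) when any margin is zero, and is invariant under
#' transposition.
#'
#' @param table a [contingency_2x2()].
#' @return a non-negative number.
#' @export
yates_chi2 <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  a <- as.numeric(table$a); b <- as.numeric(table$b)
  c_ <- as.numeric(table$c); d <- as.numeric(table$d)
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    stop("undefined chi-square: zero margin")
  }
  n <- r1 + r2
  dev <- max(0, abs(a * d - b * c_) - n / 2)
  n * dev^2 / (r1 * r2 * c1 * c2)
}

#' Signal-calling criteria
#'
#' The conventional pharmacovigilance thresholds: at least 3 co-reports,
#' PRR >= 3 and Yates chi-square >= 4, all boundaries inclusive.
#'
#' @param min_reports minimum co-report count (cell `a`).
#' @param min_prr minimum proportional reporting ratio.
#' @param min_chi2 minimum Yates chi-square statistic.
#' @return a `signal_criteria` list.
#' @export
signal_criteria <- function(min_reports = 3, min_prr = 3, min_chi2 = 4) {
  if (min_reports <= 0 || min_prr <= 0 || min_chi2 <= 0) {
    stop("all signal criteria must be > 0")
  }
  structure(list(min_reports = min_reports, min_prr = min_prr,
                 min_chi2 = min_chi2), class = "signal_criteria")
}

#' Disproportionality statistics for every observed medication-term pair
#'
#' Vectorized equivalent of building [build_pair_table()], [prr()] and
#' [yates_chi2()] for each medication / side-effect pair with at least one
#' co-report. Pairs whose table has a zero margin get `NA` chi-square (and can
#' therefore never be called signals).
#'
#' @param db a report `data.table`, already filtered to single-medication
#'   reports.
#' @param criteria a [signal_criteria()] used to set the `is_signal` flag.
#' @return a `data.table` with one row per observed pair: cells `a`-`d`,
#'   `n_reports` (= `a`), `prr`, `chi2_yates`, `is_signal`.
#' @export
disproportionality <- function(db, criteria = signal_criteria()) {
  report_id <- medication_id <- term_id <- NULL
  se <- unique(db[db$term_role == "side_effect",
                  c("report_id", "medication_id", "term_id")])
  if (nrow(se) == 0L) stop("no side-effect rows in the database")
  n <- data.table::uniqueN(se$report_id)
  med_n <- se[, list(n_med = data.table::uniqueN(report_id)),
              by = medication_id]
  term_n <- se[, list(n_term = data.table::uniqueN(report_id)), by = term_id]
  pairs <- se[, list(a = data.table::uniqueN(report_id)),
              by = c("medication_id", "term_id")]
  pairs <- merge(pairs, med_n, by = "medication_id")
  pairs <- merge(pairs, term_n, by = "term_id")
  a <- as.numeric(pairs$a)
  b <- as.numeric(pairs$n_med) - a
  c_ <- as.numeric(pairs$n_term) - a
  d <- n - a - b - c_
  # a*(c+d) / ((a+b)*c) is exact for integer-valued cells, so criteria
  # boundaries like PRR = 3 compare cleanly
  prr_v <- (a * (c_ + d)) / ((a + b) * c_)
  prr_v[c_ == 0 & a > 0] <- Inf
  prr_v[a == 0 & c_ > 0] <- 0
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  dev <- pmax(0, abs(a * d - b * c_) - n / 2)
  chi2 <- n * dev^2 / (r1 * r2 * c1 * c2)
  chi2[r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0] <- NA_real_
  out <- data.table::data.table(
    medication_id = pairs$medication_id, term_id = pairs$term_id,
    a = as.integer(a), b = as.integer(b), c = as.integer(c_),
    d = as.integer(d), n_reports = as.integer(a),
    prr = prr_v, chi2_yates = chi2
  )
  out$is_signal <- !is.na(chi2) &
    a >= criteria$min_reports &
    prr_v >= criteria$min_prr &
    chi2 >= criteria$min_chi2
  data.table::setorder(out, medication_id, term_id)
  out[]
}

#' Call disproportionality signals and define the propsychotic set
#'
#' Implements the four-step procedure: (already-filtered) single-medication
#' reports are scanned for every observed medication / side-effect pair;
#' the three disproportionality criteria are evaluated on all reports; and
#' only then are the signals restricted to the psychosis term set and
#' medications outside the exclusion (antipsychotic) set. Propsychotics are
#' the non-excluded medications with at least one psychosis-term signal.
#'
#' @param db a report `data.table`, already filtered to single-medication
#'   reports (see [filter_single_med_reports()]).
#' @param psychosis_terms character vector of psychosis term ids (must be
#'   non-empty).
#' @param excluded_meds character vector of medications to exclude
#'   (antipsychotics); may be empty.
#' @param criteria a [signal_criteria()].
#' @return a list with `propsychotics` (sorted medication ids), `signals`
#'   (all evaluated pairs with statistics and `is_signal`), and
#'   `psychosis_signals` (the signal rows that survive both filters).
#' @export
call_signals <- function(db, psychosis_terms, excluded_meds = character(),
                         criteria = signal_criteria()) {
  if (length(psychosis_terms) == 0L) {
    stop("psychosis term set must be non-empty")
  }
  stats <- disproportionality(db, criteria)
  hits <- stats[stats$is_signal &
                  stats$term_id %in% psychosis_terms &
                  !stats$medication_id %in% excluded_meds]
  list(
    propsychotics = sort(unique(hits$medication_id)),
    signals = stats,
    psychosis_signals = hits
  )
}
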