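# Set-overlap statistics: fold enrichment, hypergeometric upper tail, and
# Fisher's exact test on the induced 2x2 table.

check_overlap_input <- function(n1, n2, k, N) {
  for (v in list(n1 = n1, n2 = n2, k = k, N = N)) {
    if (length(v) != 1L || !is.numeric(v) || is.na(v) || v < 0 ||
        v != round(v)) {
      stop("overlap inputs must be single non-negative integers")
    }
  }
  if (n1 > N || n2 > N) stop("set sizes cannot exceed the universe")
  if (k > min(n1, n2)) stop("overlap cannot exceed either set size")
  if (k < max(0, n1 + n2 - N)) {
    stop("overlap below the minimum forced by the universe size")
  }
  invisible(TRUE)
}

#' Fold enrichment of an observed set overlap
#'
#' Observed overlap divided by the overlap expected by chance:
#' `k * N / (n1 * n2)`.
#'
#' @param n1,n2 sizes of the two sets.
#' @param k observed overlap.
#' @param N universe size. The universe is always an explicit argument:
#'   there is no sensible hidden default.
#' @return a non-negative number.
#' @export
fold_enrichment <- function(n1, n2, k, N) {
  check_overlap_input(n1, n2, k, N)
  if (n1 == 0 || n2 == 0 || N == 0) stop("zero margin in fold enrichment")
  k * N / (n1 * n2)
}

#' Hypergeometric upper-tail overlap test
#'
#' P(X >= k) for X hypergeometric with population `N`, `n1` successes and
#' `n2` draws: the probability of an overlap at least as large as observed
#' under random draws.
#'
#' @inheritParams fold_enrichment
#' @return a probability.
#' @export
hypergeom_overlap_test <- function(n1, n2, k, N) {
  check_overlap_input(n1, n2, k, N)
  stats::phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
}

#' Fisher's exact test for a set overlap
#'
#' Builds the 2x2 table `(k, n1-k, n2-k, N-n1-n2+k)` and returns the
#' conditional maximum-likelihood odds ratio and two-sided exact p-value,
#' following the `stats::fisher.test()` convention (two-sided p by the
#' point-probability method). Degenerate zero cells yield an infinite or
#' zero odds ratio rather than pseudo-counts.
#'
#' @inheritParams fold_enrichment
#' @return a list with `odds_ratio` and `p_value`.
#' @export
fisher_overlap_test <- function(n1, n2, k, N) {
  check_overlap_input(n1, n2, k, N)
  tab <- matrix(c(k, n1 - k, n2 - k, N - n1 - n2 + k), 2, 2)
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' All overlap statistics in one call
#'
#' @inheritParams fold_enrichment
#' @return a one-row `data.table` with `n1`, `n2`, `k`, `N`, `fold`,
#'   `hypergeom_p`, `fisher_or`, `fisher_p`.
#' @export
overlap_test <- function(n1, n2, k, N) {
  check_overlap_input(n1, n2, k, N)
  ft <- fisher_overlap_test(n1, n2, k, N)
  data.table::data.table(
    n1 = n1, n2 = n2, k = k, N = N,
    fold = if (n1 > 0 && n2 > 0) fold_enrichment(n1, n2, k, N) else NA_real_,
    hypergeom_p = hypergeom_overlap_test(n1, n2, k, N),
    fisher_or = ft$odds_ratio,
    fisher_p = ft$p_value
  )
}
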