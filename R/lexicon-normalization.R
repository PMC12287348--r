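# Simplified medical-lexicon string normalization: preprocessing, the
# edit-distance ratio family (plain / token-sort / token-set / weighted),
# exact-then-fuzzy mapping, and windowed precision-based threshold
# calibration.

#' Preprocess a clinical concept string
#'
#' Applies, in order: (1) lowercase; (2) whitespace and special characters
#' converted to a period; (3) runs of two or more periods collapsed to one;
#' (4) leading/trailing whitespace (and the boundary periods produced by
#' rule 2) stripped. Idempotent.
#'
#' @param s character vector.
#' @return character vector of normalized strings.
#' @export
#' @examples
#' preprocess_term("Schizophrenia, NOS") # "schizophrenia.nos"
preprocess_term <- function(s) {
  x <- tolower(as.character(s))
  x <- gsub("[^a-z0-9]", ".", x)
  x <- gsub("\\.{2,}", ".", x)
  x <- gsub("^\\.+|\\.+$", "", trimws(x))
  x
}

split_chars <- function(s) {
  if (nchar(s) == 0L) character() else strsplit(s, "", fixed = TRUE)[[1]]
}

# Leftmost longest common substring of two character vectors; returns
# c(i, j, len) of the block start positions and length (len 0 if none).
longest_block <- function(x, y) {
  nx <- length(x); ny <- length(y)
  best <- c(0L, 0L, 0L)
  if (nx == 0L || ny == 0L) return(best)
  prev <- integer(ny)
  for (i in seq_len(nx)) {
    cur <- integer(ny)
    hit <- which(y == x[i])
    for (j in hit) {
      cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
      if (cur[j] > best[3L]) best <- c(i - cur[j] + 1L, j - cur[j] + 1L, cur[j])
    }
    prev <- cur
  }
  best
}

# Total matched characters under the longest-matching-block decomposition:
# take the longest common substring, then recurse on the flanks.
matching_chars <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) return(0L)
  b <- longest_block(x, y)
  if (b[3L] == 0L) return(0L)
  left <- matching_chars(x[seq_len(b[1L] - 1L)], y[seq_len(b[2L] - 1L)])
  right <- matching_chars(
    x[seq_len(length(x)) > b[1L] + b[3L] - 1L],
    y[seq_len(length(y)) > b[2L] + b[3L] - 1L]
  )
  b[3L] + left + right
}

ratio_one_way <- function(s1, s2) {
  n <- nchar(s1) + nchar(s2)
  if (n == 0L) return(1)
  2 * matching_chars(split_chars(s1), split_chars(s2)) / n
}

plain_ratio <- function(s1, s2) {
  # block decomposition tie-breaks can differ by argument order; taking the
  # max of both orders guarantees symmetry
  max(ratio_one_way(s1, s2), ratio_one_way(s2, s1))
}

tokens_of <- function(s) {
  t <- strsplit(s, ".", fixed = TRUE)[[1]]
  t[nzchar(t)]
}

token_sort_string <- function(s) paste(sort(tokens_of(s)), collapse = ".")

token_sort_ratio <- function(s1, s2) {
  plain_ratio(token_sort_string(s1), token_sort_string(s2))
}

token_set_ratio <- function(s1, s2) {
  t1 <- sort(unique(tokens_of(s1)))
  t2 <- sort(unique(tokens_of(s2)))
  common <- intersect(t1, t2)
  r1 <- setdiff(t1, t2)
  r2 <- setdiff(t2, t1)
  s0 <- paste(common, collapse = ".")
  sa <- paste(c(common, r1), collapse = ".")
  sb <- paste(c(common, r2), collapse = ".")
  max(plain_ratio(s0, sa), plain_ratio(s0, sb), plain_ratio(sa, sb))
}

#' Default weights for the weighted similarity score
#'
#' The combined score is the maximum of the per-method scores after
#' multiplying token-based scores by a mild discount, mirroring the
#' convention of the cited edit-distance ratio family (whose exact weights
#' are unpublished; these defaults are configurable).
#' @export
DEFAULT_SIMILARITY_WEIGHTS <- c(plain = 1, token_sort = 0.95,
                                token_set = 0.95)

#' Similarity score between two preprocessed strings
#'
#' All methods derive from the shared-character ratio
#' `2 * matched / (nchar(s1) + nchar(s2))`, where matched characters are
#' counted over the longest-matching-block decomposition. `"plain"` scores
#' the raw strings; `"token_sort"` scores after sorting the period-delimited
#' tokens (so permuted word orders score 1); `"token_set"` augments the token
#' intersection with each string's remainder and takes the best of the three
#' comparisons (so a string containing the other scores 1); `"weighted"`
#' returns the best weighted method score. Scores are in \[0, 1\], symmetric,
#' and equal 1 on identical inputs.
#'
#' @param s1,s2 strings (preprocess with [preprocess_term()] first).
#' @param method one of `"plain"`, `"token_sort"`, `"token_set"`,
#'   `"weighted"`.
#' @param weights named weights for `"weighted"`.
#' @return a similarity score in \[0, 1\].
#' @export
similarity_ratio <- function(s1, s2,
                             method = c("plain", "token_sort", "token_set",
                                        "weighted"),
                             weights = DEFAULT_SIMILARITY_WEIGHTS) {
  method <- match.arg(method)
  switch(method,
    plain = plain_ratio(s1, s2),
    token_sort = token_sort_ratio(s1, s2),
    token_set = token_set_ratio(s1, s2),
    weighted = max(
      weights[["plain"]] * plain_ratio(s1, s2),
      weights[["token_sort"]] * token_sort_ratio(s1, s2),
      weights[["token_set"]] * token_set_ratio(s1, s2)
    )
  )
}

#' Map query terms to a vocabulary by exact then fuzzy matching
#'
#' Queries and vocabulary are preprocessed; exact matches bypass scoring
#' (method `"exact"`, score 1). Each remaining query is scored against every
#' candidate per fuzzy method and gets its best-scoring candidate, retained
#' (`mapped = TRUE`) only when the score reaches the method threshold.
#'
#' @param queries character vector of raw query terms.
#' @param vocabulary character vector of raw vocabulary terms (non-empty).
#' @param thresholds named numeric vector of per-method retention thresholds.
#' @param weights weights for the weighted method.
#' @return a `data.table` with `query`, `method`, `candidate`, `score`,
#'   `mapped`; one exact row per exactly-matched query, otherwise one row per
#'   query x method.
#' @export
exact_then_fuzzy_map <- function(queries, vocabulary,
                                 thresholds = c(plain = 0.8,
                                                token_sort = 0.8,
                                                token_set = 0.8,
                                                weighted = 0.8),
                                 weights = DEFAULT_SIMILARITY_WEIGHTS) {
  if (length(vocabulary) == 0L) stop("vocabulary must be non-empty")
  q_norm <- preprocess_term(queries)
  v_norm <- preprocess_term(vocabulary)
  rows <- list()
  exact_idx <- match(q_norm, v_norm)
  for (i in seq_along(queries)) {
    if (!is.na(exact_idx[i])) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        query = queries[i], method = "exact",
        candidate = vocabulary[exact_idx[i]], score = 1, mapped = TRUE
      )
      next
    }
    for (m in names(thresholds)) {
      scores <- vapply(v_norm, function(v) {
        similarity_ratio(q_norm[i], v, method = m, weights = weights)
      }, numeric(1))
      best <- which.max(scores)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        query = queries[i], method = m, candidate = vocabulary[best],
        score = unname(scores[best]),
        mapped = unname(scores[best]) >= thresholds[[m]]
      )
    }
  }
  data.table::rbindlist(rows)
}

#' Calibrate per-method score thresholds by windowed review
#'
#' Emulates the published review design on labeled data: per method, matches
#' are sampled in batches of up to `batch` from each score window of width
#' 0.1 starting at 0.5 (the top window closes at 1), up to `max_per_method`
#' reviewed matches; window precision is the fraction of reviewed matches
#' that are true. The chosen threshold is the lowest window lower bound whose
#' cumulative precision (over reviewed matches at or above that bound) is at
#' least `min_precision`; `NA` when no bound qualifies.
#'
#' @param matches a `data.table` as from [exact_then_fuzzy_map()] (fuzzy rows
#'   with `method` and `score`).
#' @param labels logical vector, one truth label per row of `matches`.
#' @param batch per-window sample size.
#' @param max_per_method cap on reviewed matches per method.
#' @param min_precision cumulative precision required of the chosen
#'   threshold.
#' @param seed integer seed for the sampling.
#' @return a `data.table` with one row per (method, window): `method`,
#'   `window_lower`, `window_upper`, `n_reviewed`, `n_true`, `precision`,
#'   `chosen_threshold` (repeated within method).
#' @export
calibrate_thresholds <- function(matches, labels, batch = 10L,
                                 max_per_method = 50L, min_precision = 0.9,
                                 seed = 1L) {
  stopifnot(nrow(matches) == length(labels))
  lowers <- seq(0.5, 0.9, by = 0.1)
  in_window <- function(score, lb) {
    score >= lb & (if (lb >= 0.9 - 1e-9) score <= 1 else score < lb + 0.1)
  }
  methods <- setdiff(unique(matches$method), "exact")
  out <- list()
  with_seed(seed, {
    for (m in methods) {
      idx_m <- which(matches$method == m)
      reviewed <- integer(0)
      win_rows <- list()
      for (lb in rev(lowers)) { # review from the top window down
        remaining <- max_per_method - length(reviewed)
        cand <- idx_m[in_window(matches$score[idx_m], lb)]
        take <- if (remaining <= 0L || length(cand) == 0L) {
          integer(0)
        } else if (length(cand) <= min(batch, remaining)) {
          cand
        } else {
          sample(cand, min(batch, remaining))
        }
        reviewed <- c(reviewed, take)
        win_rows[[sprintf("%.1f", lb)]] <- data.table::data.table(
          method = m, window_lower = lb,
          window_upper = if (lb >= 0.9 - 1e-9) 1 else lb + 0.1,
          n_reviewed = length(take),
          n_true = sum(labels[take]),
          precision = if (length(take)) mean(labels[take]) else NA_real_
        )
      }
      wins <- data.table::rbindlist(win_rows)
      # cumulative precision over reviewed matches at or above each bound
      chosen <- NA_real_
      for (lb in lowers) {
        above <- reviewed[matches$score[reviewed] >= lb]
        if (length(above) && mean(labels[above]) >= min_precision) {
          chosen <- lb
          break
        }
      }
      wins$chosen_threshold <- chosen
      out[[m]] <- wins
    }
  })
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L || all(res$n_reviewed == 0L)) {
    warning("no matches fell in any calibration window")
  }
  data.table::setorder(res, method, window_lower)
  res[]
}
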