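# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the global RNG state, seeds the Mersenne-Twister with `seed`,
#' evaluates `expr`, and restores the previous state so seeded package
#' functions never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Named sub-streams derived from one user-facing seed. Each generator mixes
# the master seed with a fixed per-stream offset so components can be
# regenerated independently and deterministically. Result stays < 2^31.
sub_seed <- function(seed, stream) {
  offsets <- c(
    reports = 11, links = 23, risk = 37,
    perm_prop = 71, perm_anti = 83, moa_prop = 97, moa_anti = 101,
    calibration = 67, pipeline = 53
  )
  if (!stream %in% names(offsets)) {
    stop("unknown seed sub-stream: ", stream)
  }
  as.integer((abs(as.numeric(seed)) * 127 + offsets[[stream]] * 7919) %% 2147483647)
}

assert_count <- function(x, name, min = 0) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    stop(name, " must be a single integer >= ", min, call. = FALSE)
  }
  invisible(TRUE)
}

assert_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a single number in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}
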