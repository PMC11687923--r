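#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage child seed from a global seed
#'
#' A single pipeline seed fans out deterministically to one child seed per
#' stage, so any stage can be re-run in isolation with the same randomness.
#' The derivation hashes the stage name into a 31-bit integer mixed with the
#' global seed.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character scalar).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "gwas")
child_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  out <- (as.numeric(seed) %% 2147483647) * 48271 + h
  as.integer(out %% 2147483646 + 1)
}

stop_arg <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lo = -Inf, hi = Inf,
                         lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_arg(sprintf("`%s` must be a finite numeric scalar", name))
  }
  bad_lo <- if (lo_open) x <= lo else x < lo
  bad_hi <- if (hi_open) x >= hi else x > hi
  if (bad_lo || bad_hi) {
    stop_arg(sprintf(
      "`%s` = %g outside its domain %s%g, %g%s", name, x,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
    ))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop_arg(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}
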