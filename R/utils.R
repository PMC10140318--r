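# Internal helpers shared across modules.

# column names used inside ggplot2::aes()
utils::globalVariables(c("time_h", "afu_per_ml", "population", "g_per_l",
                         "compound", "mean_fsc_h", "condition",
                         "survivability_pct"))

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator, runs `expr`, and restores the caller's RNG state so
#' that seeded simulations never perturb the global random stream.
#'
#' @param seed integer seed (must be < 2^31).
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (abs(seed) >= .Machine$integer.max) {
    stop("seed must fit in a 32-bit integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  expr
}

# Deterministic expansion of a base seed into sub-seeds (per sample, per
# restart, ...). Kept below 2^31 so set.seed() always accepts them.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483629)
}

# Consistent stop() with sprintf formatting and no call noise.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Consistent warning() with sprintf formatting.
warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is_scalar_number(x)) abort("'%s' must be a single finite number", name)
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    abort("'%s' must be %s %s (got %s)", name,
          if (strict) ">" else ">=", format(lower), format(x))
  }
  invisible(x)
}
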