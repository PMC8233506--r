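#' @keywords internal
"_PACKAGE"

# Shared argument checks. All validators stop() with the offending argument
# name so errors surface at the user-facing call.

abort_arg <- function(name, msg) {
  stop(sprintf("`%s` %s", name, msg), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_boundary = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_arg(name, "must be a single finite number")
  }
  ok <- if (allow_boundary) x >= lower && x <= upper else x > lower && x < upper
  if (!ok) {
    abort_arg(name, sprintf("must be in %s%g, %g%s",
                            if (allow_boundary) "[" else "(",
                            lower, upper,
                            if (allow_boundary) "]" else ")"))
  }
  x
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x != round(x)) {
    abort_arg(name, sprintf("must be a single integer >= %d", lower))
  }
  as.integer(x)
}

check_probability <- function(x, name) check_number(x, name, 0, 1)

#' Evaluate an expression under a local, explicit random seed
#'
#' All stochastic functions in this package take an explicit `seed` argument
#' and restore the caller's RNG state afterwards; a global seed is never
#' consumed or mutated.
#'
#' @param seed Single integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  seed <- check_count(seed, "seed")
  withr::with_seed(seed, expr)
}

# Deterministic stream of sub-seeds derived from one master seed, so nested
# stochastic stages (e.g. replicates within a sweep) stay independent and
# reproducible. Values stay below 2^31.
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
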