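#' @keywords internal
"_PACKAGE"

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators are pure functions of (parameters, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

# Deterministic sub-seed for (species i, replicate j, voltage k) streams.
# Mixing keeps results below 2^31 - 1 so set.seed() accepts them.
sub_seed <- function(base_seed, i, j = 0L, k = 0L) {
  m <- 2147483647
  s <- (as.numeric(base_seed) %% m)
  s <- (s + 1000003 * i + 7919 * j + 104729 * k) %% m
  as.integer(s)
}

stop_ciufold <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_ciufold("`%s` must be a finite numeric scalar", name)
  }
  if (positive && x <= 0) {
    stop_ciufold("`%s` must be > 0 (got %g)", name, x)
  }
  invisible(x)
}
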