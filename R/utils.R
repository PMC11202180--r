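# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic entry points route through
# this so that generators are pure functions of (spec, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

# Derive a child seed from a base seed and an index, staying within the
# 32-bit integer range R requires of set.seed().
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 10007 + i * 7919) %% 2147483647L)
}

check_series <- function(x, min_len = 2L, arg = "series") {
  if (!is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric vector", arg), call. = FALSE)
  }
  if (length(x) < min_len) {
    stop(sprintf("`%s` must have at least %d samples", arg, min_len),
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  invisible(x)
}
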