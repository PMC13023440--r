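## Internal helpers: error classes and seed discipline.

abort_nact <- function(class, msg, ...) {
  cnd <- structure(
    class = c(class, "nactsig_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cnd)
}

## All user-facing randomness goes through this: a NULL seed uses (and
## advances) the caller's RNG stream; an integer seed gives an isolated,
## reproducible stream (Mersenne-Twister, R's default) and leaves the
## caller's stream untouched.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
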