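# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a reproducible child seed from a master seed and a stream label.
# Keeps results below 2^31 so set.seed() always accepts them.
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(master) * 7919 + h * 104729) %% .Machine$integer.max)
}

stop_coexloc <- function(msg, class, ...) {
  stop(errorCondition(msg, class = c(class, "coexloc_error"), ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x)
}
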