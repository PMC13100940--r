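# Internal helpers shared across modules.

# Run expr with the RNG seeded at `seed`, restoring the caller's RNG state
# afterwards so package functions never perturb the user's random stream.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# scalar checks used by the validators
is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == round(x)
}

is_number <- function(x, min = -Inf) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min
}

`%||%` <- function(a, b) if (is.null(a)) b else a
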