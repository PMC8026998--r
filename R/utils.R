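# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators behave as pure functions of (params, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based substream derivation: a top-level seed fans out to
# per-channel / per-group seeds so that subsets of channels are reproducible
# independently of how many siblings were generated. Kept below 2^31 - 1.
sub_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(counter) * 104729
  as.integer(s %% 2147483629) + 1L
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
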