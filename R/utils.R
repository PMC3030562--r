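# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All exported stochastic functions route through this so results are pure
# functions of (arguments, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      abort("`seed` must be a single integer or NULL.")
    }
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Fixed documented derivation of per-stream seeds from a master seed, so
# e.g. each ChIP sample gets an independent reproducible stream.
# seed_i = (master + 1000003 * i) mod (2^31 - 115), kept strictly positive.
derive_seed <- function(master, index) {
  if (is.null(master)) return(NULL)
  m <- 2147483533
  as.integer((as.numeric(master) %% m + 1000003 * as.numeric(index)) %% m + 1)
}

# Stable content hash of a configuration (FNV-1a over its serialization),
# recorded in pipeline outputs for provenance.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, min))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) abort(sprintf("`%s` must be a proportion in %s.", name,
                         if (open) "(0, 1)" else "[0, 1]"))
  invisible(as.numeric(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
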