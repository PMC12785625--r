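# Internal helpers shared across modules.

# Derive a reproducible sub-seed for a named stream of randomness, so each
# generator module can be driven independently from one master seed. Kept
# below 2^31 - 1 so it is always a valid integer seed.
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483646 + 1)
}

# Evaluate `code` under a seed derived from (seed, name), restoring the
# caller's RNG state afterwards.
with_substream <- function(seed, name, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(code)
}

# Row variances without a matrixStats dependency.
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(0, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)
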