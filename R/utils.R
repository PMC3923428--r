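#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# All stochastic operations in the package route their `seed` argument here so
# a run never disturbs the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
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
  force(code)
}

# Derive a deterministic child seed from a root seed and a stream name, so
# independent pipeline stages draw from independent, reproducible streams.
# Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# m/z labels are reported to 1 decimal place throughout
mz_label <- function(mz) sprintf("%.1f", mz)

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
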