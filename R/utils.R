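#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state. If `seed` is NULL the current stream
# is used (and advanced); otherwise the global stream is left untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seeds below 2^31, so per-bin / per-repeat RNG streams
# can be re-created independently of evaluation order.
derive_seed <- function(master, ...) {
  offs <- c(...)
  x <- as.double(master %% 2147483647L)
  for (o in offs) {
    x <- (x * 48271 + as.double(o) + 1) %% 2147483647
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
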