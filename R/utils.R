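#' @keywords internal
"_PACKAGE"

## Classed conditions so callers/tests can distinguish failure modes.
abort_enctsf <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "enctsf_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort_enctsf(sprintf("%s must be numeric and finite (no NA/NaN/Inf)", what),
                 "enctsf_validation_error")
  }
  invisible(x)
}

check_count <- function(x, what, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != as.integer(x)) {
    abort_enctsf(sprintf("%s must be a single integer >= %d", what, min),
                 "enctsf_validation_error")
  }
  as.integer(x)
}

## Evaluate `expr` under a given seed without disturbing the caller's RNG
## stream. All stochastic operations in the package go through this.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

## Derive a stream-specific child seed from a base seed; keeps results
## independent across uses while staying inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 1009 + stream * 9973) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
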