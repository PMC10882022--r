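#' Sample a random Gaussian projection key
#'
#' Draws an `n x n` projection matrix `R` with i.i.d. entries from
#' `N(0, 1/n)`. Multiplying segments by `R` projects them into a random
#' subspace while (in expectation) preserving their squared norm, the
#' Johnson-Lindenstrauss-style property of this sampling law. The matrix is
#' the shared secret: two sites holding the same key file encode
#' identically. Note the matrix is square -- this is deliberate obfuscation,
#' not dimensionality reduction.
#'
#' @param n Segment length (matrix dimension), default 4.
#' @param seed Integer seed; the draw is reproducible, but the stored matrix
#'   (not the seed) is the authoritative key content.
#' @param key_id Optional identifier; autogenerated from method/n/seed if
#'   omitted.
#' @return An object of class `projection_key` with fields `matrix`, `n`,
#'   `key_id`, `seed`.
#' @examples
#' key <- sample_projection_key(4, seed = 1)
#' dim(key$matrix)
#' @export
sample_projection_key <- function(n = 4, seed = 1, key_id = NULL) {
  n <- check_count(n, "projection dimension n")
  R <- with_seed(seed, matrix(stats::rnorm(n * n, mean = 0, sd = sqrt(1 / n)), n, n))
  structure(list(matrix = R, n = n,
                 key_id = key_id %||% sprintf("proj-n%d-s%d", n, as.integer(seed)),
                 seed = as.integer(seed), scaling = NULL),
            class = c("projection_key", "encoding_key"))
}

#' @export
print.projection_key <- function(x, ...) {
  cat(sprintf("<projection_key '%s': %dx%d Gaussian N(0, 1/%d) matrix>\n",
              x$key_id, x$n, x$n, x$n))
  invisible(x)
}

#' Encode one segment by random projection
#'
#' Computes `R %*% seg` exactly (double precision, no normalization or
#' rounding). The encoded segment has the same length as the input.
#'
#' @param seg Numeric vector of length `key$n`.
#' @param key A `projection_key`.
#' @return Numeric vector of length `key$n`.
#' @examples
#' key <- sample_projection_key(4, seed = 7)
#' project_segment(c(0.1, 0.2, 0.3, 0.4), key)
#' @export
project_segment <- function(seg, key) {
  stopifnot(inherits(key, "projection_key"))
  if (length(seg) != key$n) {
    abort_enctsf(sprintf("segment length %d does not match key dimension n=%d",
                         length(seg), key$n), "enctsf_shape_error")
  }
  check_finite(seg, "segment")
  as.vector(key$matrix %*% seg)
}

## Segment-encoder generic: maps an n x M matrix of segments (one per
## column) to an n x M matrix of encoded segments.
encode_segments <- function(key, segmat, ...) UseMethod("encode_segments")

#' @export
encode_segments.projection_key <- function(key, segmat, ...) {
  if (nrow(segmat) != key$n) {
    abort_enctsf(sprintf("segment rows %d do not match key dimension n=%d",
                         nrow(segmat), key$n), "enctsf_shape_error")
  }
  key$matrix %*% segmat
}
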