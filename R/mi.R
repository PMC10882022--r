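#' Reduce a time series to a vector for mutual-information estimation
#'
#' `"averaged"` takes the per-feature mean over time (length `F`);
#' `"vectorized"` flattens the matrix row-major, i.e. feature by feature in
#' time order (length `F*T`). With `T = 1` the two coincide.
#'
#' @param X An `mts_example`.
#' @param mode `"averaged"` or `"vectorized"`.
#' @return Numeric vector.
#' @examples
#' X <- mts_example(matrix(c(1, 2, 3, 4), 2, 2))
#' reduce_inputs(X, "averaged")    # rowMeans
#' reduce_inputs(X, "vectorized")  # row-major flatten
#' @export
reduce_inputs <- function(X, mode = c("averaged", "vectorized")) {
  mode <- match.arg(mode)
  stopifnot(inherits(X, "mts_example"))
  if (mode == "averaged") unname(rowMeans(X$values)) else as.vector(t(X$values))
}

## Chebyshev (max-norm) k-th nearest neighbour distances and neighbour
## counts, computed in row chunks to bound memory. D(i, j) over a set of
## columns is built by pmax-accumulation across dimensions.
cheb_dist_chunk <- function(A, B) {
  ## A: m x d chunk, B: n x d full set; returns m x n max-norm distances
  m <- nrow(A); n <- nrow(B)
  D <- matrix(0, m, n)
  for (j in seq_len(ncol(A))) {
    D <- pmax(D, abs(outer(A[, j], B[, j], "-")))
  }
  D
}

#' Kraskov-Stoegbauer-Grassberger mutual-information estimate
#'
#' Nonparametric kNN estimator (KSG variant 1) of the mutual information
#' between two continuous vector samples, in nats:
#' `MI = digamma(k) + digamma(N) - mean(digamma(nx+1) + digamma(ny+1))`,
#' where `eps_i` is the Chebyshev distance to the `k`-th neighbour in the
#' joint space and `nx`, `ny` count strictly closer marginal neighbours.
#' Columns are standardized (training-free, per sample) before estimation
#' so the max-norm treats all coordinates comparably. Exactly duplicated
#' points make the kNN distance degenerate; in that case a seeded jitter of
#' relative scale 1e-10 is added and the estimate recomputed.
#'
#' @param x,y Numeric matrices (or vectors) with one row per example.
#' @param k Neighbour count, default 3; requires `N >= 2k + 2`.
#' @param input_reduction Optional tag (`"averaged"`/`"vectorized"`)
#'   recorded in the result.
#' @param jitter_seed Seed for the duplicate-breaking jitter.
#' @return An object of class `mi_estimate`: list with `value` (nats),
#'   `k`, `n`, `input_reduction`.
#' @examples
#' set.seed(1)
#' estimate_mi(rnorm(500), rnorm(500))$value  # near 0
#' @export
estimate_mi <- function(x, y, k = 3, input_reduction = NULL, jitter_seed = 1) {
  x <- as.matrix(x); y <- as.matrix(y)
  k <- check_count(k, "k")
  N <- nrow(x)
  if (nrow(y) != N) abort_enctsf("x and y must have equal sample counts", "enctsf_validation_error")
  if (N < 2 * k + 2) {
    abort_enctsf(sprintf("need at least 2k+2 = %d samples, got %d", 2 * k + 2, N),
                 "enctsf_validation_error")
  }
  standardize <- function(M) {
    s <- apply(M, 2, stats::sd)
    keep <- s > 0 & is.finite(s)
    if (!any(keep)) return(M[, 1, drop = FALSE] * 0)
    scale(M[, keep, drop = FALSE])
  }
  xs <- standardize(x); ys <- standardize(y)
  val <- ksg1(xs, ys, k)
  if (!is.finite(val)) {
    jit <- function(M) M + matrix(stats::rnorm(length(M), 0, 1e-10), nrow(M))
    val <- with_seed(jitter_seed, ksg1(jit(xs), jit(ys), k))
  }
  structure(list(value = val, k = k, n = N, input_reduction = input_reduction),
            class = "mi_estimate")
}

ksg1 <- function(xs, ys, k, chunk = 256L) {
  N <- nrow(xs)
  nx <- integer(N); ny <- integer(N); degenerate <- FALSE
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(N, start + chunk - 1L)
    Dx <- cheb_dist_chunk(xs[idx, , drop = FALSE], xs)
    Dy <- cheb_dist_chunk(ys[idx, , drop = FALSE], ys)
    Dz <- pmax(Dx, Dy)
    for (r in seq_along(idx)) {
      i <- idx[r]
      dz <- Dz[r, ]; dz[i] <- Inf
      eps <- sort.int(dz, partial = k)[k]
      if (eps == 0) { degenerate <- TRUE; break }
      nx[i] <- sum(Dx[r, ] < eps) - 1L
      ny[i] <- sum(Dy[r, ] < eps) - 1L
    }
    if (degenerate) break
  }
  if (degenerate) return(NaN)
  digamma(k) + digamma(N) - mean(digamma(nx + 1) + digamma(ny + 1))
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate: %.4f nats (k=%d, n=%d%s)>\n", x$value, x$k, x$n,
              if (!is.null(x$input_reduction)) paste0(", ", x$input_reduction) else ""))
  invisible(x)
}
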