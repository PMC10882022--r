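#' Multivariate time series
#'
#' Container for one example: an `F x T` real matrix, one row per feature
#' (1-d signal), one column per uniformly spaced time step. All entries must
#' be finite; imputation of missing values is an upstream concern.
#'
#' @param values Numeric matrix, `F` rows (features) by `T` columns (time).
#' @param feature_names Character vector of `F` unique feature names.
#'   Defaults to rownames of `values` or `f1..fF`.
#' @param example_id Single string identifying the example.
#' @return An object of class `mts_example`.
#' @examples
#' x <- mts_example(matrix(rnorm(8), 2, 4), c("hr", "sbp"), "icu001")
#' dim(x$values)
#' @export
mts_example <- function(values, feature_names = NULL, example_id = "example") {
  if (!is.matrix(values)) values <- rbind(values)
  storage.mode(values) <- "double"
  check_finite(values, "time-series values")
  if (nrow(values) < 1L || ncol(values) < 1L) {
    abort_enctsf("time series needs F >= 1 features and T >= 1 time steps",
                 "enctsf_validation_error")
  }
  feature_names <- feature_names %||% rownames(values) %||%
    paste0("f", seq_len(nrow(values)))
  if (length(feature_names) != nrow(values) || anyDuplicated(feature_names)) {
    abort_enctsf("feature_names must contain exactly F unique entries",
                 "enctsf_validation_error")
  }
  dimnames(values) <- list(feature_names, NULL)
  structure(list(values = values,
                 feature_names = as.character(feature_names),
                 example_id = as.character(example_id)[1]),
            class = "mts_example")
}

#' @export
print.mts_example <- function(x, ...) {
  cat(sprintf("<mts_example '%s': %d features x %d time steps>\n",
              x$example_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
as.matrix.mts_example <- function(x, ...) x$values

#' Split a 1-d signal into fixed-length segments
#'
#' Divides a length-`T` signal into consecutive chunks of length `n`. Under
#' the default `"strict"` edge policy `T` must be divisible by `n`; under
#' `"pad_zero_trim"` the signal is zero-padded up to the next multiple of
#' `n` before splitting (the encoder trims the pad again after encoding).
#'
#' @param x Numeric vector (the signal) with finite entries.
#' @param n Segment length, integer >= 1.
#' @param edge_policy `"strict"` or `"pad_zero_trim"`.
#' @return An `n x ceiling(T/n)` matrix; column `j` is segment `j`, so
#'   concatenating columns in order reproduces the (possibly padded) signal.
#' @examples
#' segment_signal(1:8, 4)        # two columns
#' segment_signal(1:6, 4, "pad_zero_trim")
#' @export
segment_signal <- function(x, n, edge_policy = c("strict", "pad_zero_trim")) {
  edge_policy <- match.arg(edge_policy)
  n <- check_count(n, "segment length n")
  check_finite(x, "signal samples")
  T_len <- length(x)
  if (T_len %% n != 0L) {
    if (edge_policy == "strict") {
      abort_enctsf(
        sprintf("signal length T=%d is not divisible by segment length n=%d (edge_policy='strict')",
                T_len, n),
        "enctsf_divisibility_error")
    }
    x <- c(x, numeric(n * ceiling(T_len / n) - T_len))
  }
  matrix(x, nrow = n)
}

#' Per-feature min-max statistics
#'
#' Computes reference minima/maxima for [0, 1] scaling, feature by feature,
#' from one example, a list of examples, or a cohort (in which case only the
#' requested split -- by default `"train"` -- is used, so the statistics can
#' be frozen into a key and reused unchanged at encoding time elsewhere).
#'
#' @param x An `mts_example`, a list of them, or a `cohort`.
#' @param split For a cohort, which split(s) to compute the statistics from.
#' @return A list with numeric vectors `min` and `max` (named by feature).
#' @export
minmax_stats <- function(x, split = "train") {
  if (inherits(x, "cohort")) {
    keep <- x$split %in% split
    if (!any(keep)) abort_enctsf("no examples in requested split", "enctsf_validation_error")
    x <- x$examples[keep]
  }
  if (inherits(x, "mts_example")) x <- list(x)
  Fdim <- nrow(x[[1]]$values)
  mn <- matrix(vapply(x, function(e) apply(e$values, 1, min), numeric(Fdim)), nrow = Fdim)
  mx <- matrix(vapply(x, function(e) apply(e$values, 1, max), numeric(Fdim)), nrow = Fdim)
  mins <- apply(mn, 1, min)
  maxs <- apply(mx, 1, max)
  names(mins) <- names(maxs) <- x[[1]]$feature_names
  check_finite(mins, "minmax statistics")
  check_finite(maxs, "minmax statistics")
  if (any(maxs < mins)) abort_enctsf("max < min in scaling statistics", "enctsf_validation_error")
  list(min = mins, max = maxs)
}

#' Min-max scale a time series to [0, 1]
#'
#' Affinely maps each feature to `[0, 1]` using reference per-feature
#' minima/maxima. Constant features (min == max) map to 0.5; values outside
#' the reference range are clipped to `[0, 1]`. Used to bound inputs before
#' quantum angle encoding so RY angles stay in `[0, pi]`.
#'
#' @param X An `mts_example`.
#' @param stats A list with vectors `min` and `max` of length `F`
#'   (see [minmax_stats()]).
#' @return A scaled `mts_example`.
#' @examples
#' x <- mts_example(matrix(c(0, 5, 10, 12), 1))
#' scale_minmax(x, list(min = 0, max = 10))$values  # 0 0.5 1 1 (clipped)
#' @export
scale_minmax <- function(X, stats) {
  stopifnot(inherits(X, "mts_example"))
  check_finite(stats$min, "scaling min")
  check_finite(stats$max, "scaling max")
  Fdim <- nrow(X$values)
  if (length(stats$min) != Fdim || length(stats$max) != Fdim) {
    abort_enctsf("scaling statistics length must equal feature count", "enctsf_validation_error")
  }
  if (any(stats$max < stats$min)) {
    abort_enctsf("max < min in scaling statistics", "enctsf_validation_error")
  }
  rng <- stats$max - stats$min
  scaled <- (X$values - stats$min) / ifelse(rng > 0, rng, 1)
  scaled[rng == 0, ] <- 0.5
  scaled <- pmin(pmax(scaled, 0), 1)
  mts_example(scaled, X$feature_names, X$example_id)
}
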