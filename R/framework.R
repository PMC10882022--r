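#' Framework configuration
#'
#' Bundles the knobs of the segment-wise encoding framework.
#'
#' @param segment_length Segment length `n`; default 4. For quantum keys it
#'   must equal the circuit's wire count.
#' @param edge_policy `"strict"` (signal length must be divisible by `n`)
#'   or `"pad_zero_trim"` (zero-pad, encode, trim back).
#' @param input_scaling `"auto"` (min-max for quantum keys, none for
#'   projection keys), `"none"`, or `"minmax_01"`. Min-max scaling keeps RY
#'   encoding angles in `[0, pi]`, where `cos` is monotone per qubit.
#' @param key_id Optional key identifier recorded on outputs.
#' @param seed Optional integer recorded for provenance.
#' @return A list of class `framework_config`.
#' @export
framework_config <- function(segment_length = 4,
                             edge_policy = c("strict", "pad_zero_trim"),
                             input_scaling = c("auto", "none", "minmax_01"),
                             key_id = NULL, seed = NULL) {
  structure(list(segment_length = check_count(segment_length, "segment_length"),
                 edge_policy = match.arg(edge_policy),
                 input_scaling = match.arg(input_scaling),
                 key_id = key_id, seed = seed),
            class = "framework_config")
}

key_method <- function(key) {
  if (inherits(key, "projection_key")) "projection"
  else if (inherits(key, "quantum_circuit")) "quantum"
  else abort_enctsf("key must be a projection_key or quantum_circuit",
                    "enctsf_configuration_error")
}

key_segment_length <- function(key) {
  if (inherits(key, "projection_key")) key$n else key$n_wires
}

resolve_scaling <- function(cfg, key) {
  if (cfg$input_scaling == "auto") {
    if (key_method(key) == "quantum") "minmax_01" else "none"
  } else cfg$input_scaling
}

check_key_cfg <- function(key, cfg) {
  if (key_segment_length(key) != cfg$segment_length) {
    abort_enctsf(sprintf("key segment size %d does not match configured segment_length %d",
                         key_segment_length(key), cfg$segment_length),
                 "enctsf_configuration_error")
  }
}

#' Encode a multivariate time series segment-wise
#'
#' Applies the key's segment transformation independently to every
#' length-`n` segment of every 1-d signal and concatenates the encoded
#' segments in time order. There is no cross-feature mixing: output row `i`
#' depends only on input row `i`. The output has exactly the input's
#' `F x T` shape (any zero pad added under `"pad_zero_trim"` is trimmed
#' after encoding), and for a fixed key the mapping is deterministic.
#'
#' @param X An `mts_example`.
#' @param key A `projection_key` or `quantum_circuit` (the shared secret).
#' @param cfg A [framework_config()].
#' @param stats Optional per-feature min/max reference statistics (see
#'   [minmax_stats()]); required when min-max scaling applies, unless the
#'   key already carries frozen statistics in `key$scaling`.
#' @return An `mts_example` with additional class `encoded_mts` and fields
#'   `key_id` and `method`; quantum-encoded values all lie in `[-1, 1]`.
#' @examples
#' X <- mts_example(matrix(runif(3 * 8), 3, 8))
#' key <- sample_projection_key(4, seed = 1)
#' E <- encode_timeseries(X, key)
#' dim(E$values)  # unchanged: 3 x 8
#' @export
encode_timeseries <- function(X, key, cfg = framework_config(), stats = NULL) {
  stopifnot(inherits(X, "mts_example"))
  check_key_cfg(key, cfg)
  n <- cfg$segment_length
  scaling <- resolve_scaling(cfg, key)
  if (scaling == "minmax_01") {
    stats <- stats %||% key$scaling
    if (is.null(stats)) {
      abort_enctsf("min-max scaling requested but no reference statistics supplied (pass `stats` or use a key with frozen scaling)",
                   "enctsf_configuration_error")
    }
    X <- scale_minmax(X, stats)
  }
  T_len <- ncol(X$values)
  V <- X$values
  if (T_len %% n != 0L) {
    if (cfg$edge_policy == "strict") {
      abort_enctsf(sprintf("signal length T=%d is not divisible by segment length n=%d (edge_policy='strict')",
                           T_len, n), "enctsf_divisibility_error")
    }
    V <- cbind(V, matrix(0, nrow(V), n * ceiling(T_len / n) - T_len))
  }
  Tp <- ncol(V)
  segmat <- matrix(t(V), nrow = n)             # columns: segments, feature-major
  enc <- encode_segments(key, segmat)
  Ev <- t(matrix(enc, nrow = Tp))[, seq_len(T_len), drop = FALSE]
  out <- mts_example(Ev, X$feature_names, X$example_id)
  out$key_id <- cfg$key_id %||% key$key_id
  out$method <- key_method(key)
  class(out) <- c("encoded_mts", class(out))
  out
}

#' Encode every example of a cohort
#'
#' Vectorized application of [encode_timeseries()] across a cohort: all
#' segments of all features of all examples are transformed in one batched
#' pass, which matters for the quantum simulator. Scaling statistics, when
#' needed and not supplied, are computed from the cohort's training split
#' only, so held-out examples are encoded with frozen reference statistics.
#'
#' @param ds A `cohort` (see [generate_cohort()]).
#' @param key A `projection_key` or `quantum_circuit`.
#' @param cfg A [framework_config()].
#' @param stats Optional min/max statistics; defaults to `key$scaling`,
#'   then to [minmax_stats()] on the training split.
#' @return A `cohort` whose examples are encoded; labels, attributes and
#'   splits are carried over unchanged, and `ds$encoding` records the
#'   key id and method.
#' @export
encode_cohort <- function(ds, key, cfg = framework_config(), stats = NULL) {
  stopifnot(inherits(ds, "cohort"))
  check_key_cfg(key, cfg)
  n <- cfg$segment_length
  scaling <- resolve_scaling(cfg, key)
  examples <- ds$examples
  if (scaling == "minmax_01") {
    stats <- stats %||% key$scaling %||% minmax_stats(ds, split = "train")
    examples <- lapply(examples, scale_minmax, stats = stats)
  }
  T_len <- ncol(examples[[1]]$values)
  Fdim <- nrow(examples[[1]]$values)
  pad <- (n - T_len %% n) %% n
  if (pad > 0L && cfg$edge_policy == "strict") {
    abort_enctsf(sprintf("signal length T=%d is not divisible by segment length n=%d (edge_policy='strict')",
                         T_len, n), "enctsf_divisibility_error")
  }
  Tp <- T_len + pad
  big <- vapply(examples, function(e) {
    V <- e$values
    if (pad > 0L) V <- cbind(V, matrix(0, Fdim, pad))
    as.vector(t(V))
  }, numeric(Tp * Fdim))
  segmat <- matrix(big, nrow = n)
  enc <- encode_segments(key, segmat)
  per_ex <- Tp * Fdim
  out_examples <- vector("list", length(examples))
  for (i in seq_along(examples)) {
    block <- enc[, ((i - 1L) * per_ex / n + 1L):(i * per_ex / n), drop = FALSE]
    Ev <- t(matrix(block, nrow = Tp))[, seq_len(T_len), drop = FALSE]
    ex <- mts_example(Ev, examples[[i]]$feature_names, examples[[i]]$example_id)
    ex$key_id <- cfg$key_id %||% key$key_id
    ex$method <- key_method(key)
    class(ex) <- c("encoded_mts", class(ex))
    out_examples[[i]] <- ex
  }
  ds$examples <- out_examples
  ds$encoding <- list(key_id = key$key_id, method = key_method(key),
                      segment_length = n, input_scaling = scaling)
  ds
}
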