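#' Write an encoding key to a JSON file
#'
#' Serializes a projection or quantum key at full double precision,
#' together with any frozen per-feature min/max scaling statistics. The key
#' file is the shareable agreement artifact between sites: it never embeds
#' raw data, only the transformation (and, for quantum keys, two summary
#' numbers per feature when scaling statistics are frozen in -- an
#' acknowledged, documented leak). Wire indices in the file are 1-based;
#' wire 1 is the most significant basis bit.
#'
#' @param key A `projection_key` or `quantum_circuit`.
#' @param path Output file path.
#' @param force Overwrite an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_key <- function(key, path, force = FALSE) {
  if (file.exists(path) && !force) {
    abort_enctsf(sprintf("refusing to overwrite existing key file '%s' (use force = TRUE)", path),
                 "enctsf_overwrite_error")
  }
  method <- key_method(key)
  obj <- list(format = "enctsf-key", format_version = 1L, method = method,
              key_id = key$key_id, seed = key$seed,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (method == "projection") {
    obj$n <- key$n
    obj$matrix_row_major <- as.vector(t(key$matrix))
  } else {
    obj$n_wires <- key$n_wires
    obj$layers <- key$layers
    obj$gates <- lapply(key$gates, function(g) {
      if (g$kind == "RX") list(kind = "RX", wire = g$wire, angle = g$angle)
      else list(kind = "CNOT", control = g$control, target = g$target)
    })
  }
  if (!is.null(key$scaling)) {
    obj$scaling <- list(min = unname(key$scaling$min), max = unname(key$scaling$max),
                        feature = names(key$scaling$min))
  }
  ## digits = I(17): 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read an encoding key from a JSON file
#'
#' @param path Path to a key file written by [write_key()].
#' @return A `projection_key` or `quantum_circuit` object.
#' @export
read_key <- function(path) {
  if (!file.exists(path)) {
    abort_enctsf(sprintf("key file '%s' does not exist", path), "enctsf_io_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "enctsf-key")) {
    abort_enctsf(sprintf("'%s' is not an enctsf key file", path), "enctsf_parse_error")
  }
  key <- if (identical(obj$method, "projection")) {
    n <- as.integer(obj$n)
    structure(list(matrix = matrix(as.numeric(unlist(obj$matrix_row_major)),
                                   n, n, byrow = TRUE),
                   n = n, key_id = obj$key_id, seed = as.integer(obj$seed %||% NA),
                   scaling = NULL),
              class = c("projection_key", "encoding_key"))
  } else if (identical(obj$method, "quantum")) {
    gates <- lapply(obj$gates, function(g) {
      if (identical(g$kind, "RX")) {
        list(kind = "RX", wire = as.integer(g$wire), angle = as.numeric(g$angle))
      } else if (identical(g$kind, "CNOT")) {
        list(kind = "CNOT", control = as.integer(g$control), target = as.integer(g$target))
      } else abort_enctsf("unknown gate kind in key file", "enctsf_parse_error")
    })
    structure(list(n_wires = as.integer(obj$n_wires), layers = as.integer(obj$layers),
                   gates = gates, key_id = obj$key_id,
                   seed = as.integer(obj$seed %||% NA), scaling = NULL),
              class = c("quantum_circuit", "encoding_key"))
  } else {
    abort_enctsf(sprintf("unknown key method '%s'", obj$method), "enctsf_parse_error")
  }
  if (!is.null(obj$scaling)) {
    mn <- as.numeric(unlist(obj$scaling$min))
    mx <- as.numeric(unlist(obj$scaling$max))
    nm <- as.character(unlist(obj$scaling$feature))
    if (length(nm) == length(mn)) names(mn) <- names(mx) <- nm
    key$scaling <- list(min = mn, max = mx)
  }
  key
}
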