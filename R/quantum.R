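## Statevector conventions
## -----------------------
## An n-qubit register is a complex vector of 2^n amplitudes. Element i
## (1-based) is the amplitude of basis state |b_1 b_2 ... b_n> where b_1 --
## the state of wire 1 -- is the MOST significant bit of i - 1. This
## ordering is fixed so that serialized circuit keys are portable.
## Single-qubit gates are applied in O(2^n) by pairing amplitude indices
## that differ only in the target wire's bit; the dense 2^n x 2^n
## unitary-product construction exists only as an independent test oracle.

wire_index_pairs <- function(n, wire) {
  stride <- 2L^(n - wire)
  k <- 0:(2L^n - 1L)
  i0 <- which((k %/% stride) %% 2L == 0L)
  list(i0 = i0, i1 = i0 + stride)
}

check_wire <- function(n, wire) {
  if (length(wire) != 1L || is.na(wire) || wire < 1L || wire > n || wire != as.integer(wire)) {
    abort_enctsf(sprintf("wire must be an integer in 1..%d", n), "enctsf_index_error")
  }
  as.integer(wire)
}

n_wires_of <- function(state) {
  n <- log2(length(state))
  if (n != as.integer(n)) {
    abort_enctsf("state vector length must be a power of 2", "enctsf_validation_error")
  }
  as.integer(n)
}

#' Initialize an n-qubit register
#'
#' Returns the statevector of `n` qubits all in the resting state
#' `|0...0>`: amplitude 1 on the first basis index, 0 elsewhere.
#'
#' @param n Number of qubits (wires), integer >= 1.
#' @return Complex vector of length `2^n`.
#' @examples
#' init_state(2)  # |00>
#' @export
init_state <- function(n) {
  n <- check_count(n, "qubit count n")
  state <- complex(2^n)
  state[1] <- 1 + 0i
  state
}

#' Single-qubit rotation about the y-axis
#'
#' Applies `RY(phi) = [[cos(phi/2), -sin(phi/2)], [sin(phi/2), cos(phi/2)]]`
#' to the designated wire of a tensor-product state. `RY(pi)` maps `|0>` to
#' `|1>`; `RY(pi/2)` prepares an equal superposition. Norm is preserved.
#'
#' @param state Complex statevector of length `2^n`.
#' @param wire Wire index in `1..n` (wire 1 = most significant basis bit).
#' @param phi Rotation angle in radians.
#' @return The rotated statevector.
#' @export
apply_ry <- function(state, wire, phi) {
  n <- n_wires_of(state)
  wire <- check_wire(n, wire)
  p <- wire_index_pairs(n, wire)
  c2 <- cos(phi / 2); s2 <- sin(phi / 2)
  a0 <- state[p$i0]; a1 <- state[p$i1]
  state[p$i0] <- c2 * a0 - s2 * a1
  state[p$i1] <- s2 * a0 + c2 * a1
  state
}

#' Single-qubit rotation about the x-axis
#'
#' Applies `RX(phi) = [[cos(phi/2), -i sin(phi/2)], [-i sin(phi/2),
#' cos(phi/2)]]` to the designated wire. `RX(0)` is the identity;
#' `RX(pi)|0> = -i|1>`.
#'
#' @inheritParams apply_ry
#' @return The rotated statevector.
#' @export
apply_rx <- function(state, wire, phi) {
  n <- n_wires_of(state)
  wire <- check_wire(n, wire)
  p <- wire_index_pairs(n, wire)
  c2 <- cos(phi / 2); s2 <- complex(real = 0, imaginary = -sin(phi / 2))
  a0 <- state[p$i0]; a1 <- state[p$i1]
  state[p$i0] <- c2 * a0 + s2 * a1
  state[p$i1] <- s2 * a0 + c2 * a1
  state
}

#' Controlled-NOT gate
#'
#' Flips the target qubit on every basis state whose control qubit is `|1>`;
#' amplitudes with control `|0>` are untouched. For two qubits this sends
#' `a|00> + b|01> + c|10> + d|11>` to `a|00> + b|01> + d|10> + c|11>`.
#'
#' @param state Complex statevector of length `2^n`.
#' @param control,target Distinct wire indices in `1..n`.
#' @return The entangled statevector (a basis permutation of the input).
#' @export
apply_cnot <- function(state, control, target) {
  n <- n_wires_of(state)
  control <- check_wire(n, control)
  target <- check_wire(n, target)
  if (control == target) {
    abort_enctsf("CNOT control and target must be distinct wires",
                 "enctsf_validation_error")
  }
  state[cnot_permutation(n, control, target)]
}

## Index permutation implementing CNOT: identity where control bit is 0,
## target-bit swap where control bit is 1.
cnot_permutation <- function(n, control, target) {
  k <- 0:(2L^n - 1L)
  cbit <- (k %/% 2L^(n - control)) %% 2L
  tstride <- 2L^(n - target)
  tbit <- (k %/% tstride) %% 2L
  k + cbit * (1L - 2L * tbit) * tstride + 1L
}

#' Pauli-Z expectation of one wire
#'
#' Returns `<Z> = P(wire = 0) - P(wire = 1)` for the designated wire,
#' marginalizing the statevector over the other qubits. This is the scalar
#' in `[-1, 1]` used as the encoded value; the simulation is exact (no shot
#' sampling) and non-destructive.
#'
#' @inheritParams apply_ry
#' @return Real number in `[-1, 1]`.
#' @examples
#' measure_z(init_state(1), 1)                  # +1
#' measure_z(apply_ry(init_state(1), 1, pi), 1) # -1
#' @export
measure_z <- function(state, wire) {
  n <- n_wires_of(state)
  wire <- check_wire(n, wire)
  p <- wire_index_pairs(n, wire)
  p0 <- sum(Mod(state[p$i0])^2)
  2 * p0 - sum(Mod(state)^2)
}

#' Build a random quantum circuit key
#'
#' Constructs the secret, data-independent part of the quantum encoder:
#' `layers` repetitions of a per-wire RX rotation with angles drawn from
#' `Uniform[0, 2*pi)` followed by a CNOT ladder (control `i`, target `i+1`
#' for `i = 1..n_wires-1`). The per-segment input-encoding RY gates are not
#' stored -- they are generated from the data at encoding time. Angles are
#' kept at full double precision; the stored gate list (not the seed) is
#' the authoritative key content.
#'
#' @param n_wires Number of wires; must equal the segment length and be
#'   >= 2 so the CNOT ladder has at least one pair.
#' @param layers Number of RX + CNOT-ladder repetitions, default 2.
#' @param seed Integer seed for the angle draws.
#' @param key_id Optional identifier.
#' @return An object of class `quantum_circuit` with fields `n_wires`,
#'   `layers`, `gates` (ordered list), `key_id`, `seed`.
#' @examples
#' circ <- build_random_circuit(4, layers = 2, seed = 42)
#' length(circ$gates)  # 8 RX + 6 CNOT
#' @export
build_random_circuit <- function(n_wires = 4, layers = 2, seed = 1, key_id = NULL) {
  n_wires <- check_count(n_wires, "n_wires")
  layers <- check_count(layers, "layers")
  if (n_wires < 2L) {
    abort_enctsf("n_wires must be >= 2 (CNOT entanglement needs a wire pair)",
                 "enctsf_validation_error")
  }
  angles <- with_seed(seed, stats::runif(layers * n_wires, 0, 2 * pi))
  gates <- list()
  g <- 0L
  for (l in seq_len(layers)) {
    for (w in seq_len(n_wires)) {
      g <- g + 1L
      gates[[g]] <- list(kind = "RX", wire = w,
                         angle = angles[(l - 1L) * n_wires + w])
    }
    for (w in seq_len(n_wires - 1L)) {
      g <- g + 1L
      gates[[g]] <- list(kind = "CNOT", control = w, target = w + 1L)
    }
  }
  structure(list(n_wires = n_wires, layers = layers, gates = gates,
                 key_id = key_id %||% sprintf("qc-n%d-l%d-s%d", n_wires, layers, as.integer(seed)),
                 seed = as.integer(seed), scaling = NULL),
            class = c("quantum_circuit", "encoding_key"))
}

#' @export
print.quantum_circuit <- function(x, ...) {
  kinds <- vapply(x$gates, `[[`, "", "kind")
  cat(sprintf("<quantum_circuit '%s': %d wires, %d layers, %d RX + %d CNOT gates>\n",
              x$key_id, x$n_wires, x$layers, sum(kinds == "RX"), sum(kinds == "CNOT")))
  invisible(x)
}

#' Run the stored circuit gates on a statevector
#'
#' Applies the key's RX and CNOT gates in order. Input-encoding RY gates
#' are not part of the stored circuit and must be applied beforehand.
#'
#' @param state Complex statevector of length `2^n_wires`.
#' @param circuit A `quantum_circuit`.
#' @return The processed statevector.
#' @export
apply_circuit <- function(state, circuit) {
  stopifnot(inherits(circuit, "quantum_circuit"))
  for (gate in circuit$gates) {
    state <- switch(gate$kind,
      RX   = apply_rx(state, gate$wire, gate$angle),
      CNOT = apply_cnot(state, gate$control, gate$target),
      abort_enctsf(sprintf("unknown gate kind '%s'", gate$kind), "enctsf_validation_error"))
  }
  state
}

#' Quantum-encode one segment
#'
#' The three-step encoding: (1) write the segment onto the wires by rotating
#' qubit `k` with `RY(pi * seg[k])`, (2) process the register with the key's
#' random circuit, (3) read out the Pauli-Z expectation of every wire. The
#' output has the segment's length and every entry lies in `[-1, 1]`.
#' Because the readout discards phase and correlation information, distinct
#' register states can produce identical outputs -- the measurement is
#' many-to-one, which is what makes this encoder non-invertible.
#'
#' @param seg Numeric vector of length `circuit$n_wires`; values are
#'   expected in `[0, 1]` when min-max scaling is configured upstream, so
#'   RY angles span `[0, pi]`.
#' @param circuit A `quantum_circuit`.
#' @return Numeric vector of per-wire `<Z>` values in `[-1, 1]`.
#' @examples
#' circ <- build_random_circuit(4, seed = 1)
#' quantum_encode_segment(c(0.2, 0.5, 0.8, 0.1), circ)
#' @export
quantum_encode_segment <- function(seg, circuit) {
  stopifnot(inherits(circuit, "quantum_circuit"))
  if (length(seg) != circuit$n_wires) {
    abort_enctsf(sprintf("segment length %d does not match circuit n_wires=%d",
                         length(seg), circuit$n_wires), "enctsf_shape_error")
  }
  check_finite(seg, "segment")
  state <- init_state(circuit$n_wires)
  for (w in seq_len(circuit$n_wires)) {
    state <- apply_ry(state, w, pi * seg[w])
  }
  state <- apply_circuit(state, circuit)
  vapply(seq_len(circuit$n_wires), function(w) measure_z(state, w), numeric(1))
}

## ---- batch path -------------------------------------------------------
## Simulates M segments at once: the register is an M x 2^n complex matrix
## (one row per segment). Column pairs are the same index pairs as the
## single-segment path; RY coefficient vectors vary per row, circuit RX
## coefficients are scalar, CNOT is a column permutation. Processes in
## chunks to bound memory.

batch_quantum_encode <- function(segmat, circuit, chunk = 65536L) {
  n <- circuit$n_wires
  if (nrow(segmat) != n) {
    abort_enctsf(sprintf("segment rows %d do not match circuit n_wires=%d",
                         nrow(segmat), n), "enctsf_shape_error")
  }
  M <- ncol(segmat)
  out <- matrix(0, n, M)
  pairs <- lapply(seq_len(n), function(w) wire_index_pairs(n, w))
  for (start in seq(1L, M, by = chunk)) {
    idx <- start:min(M, start + chunk - 1L)
    m <- length(idx)
    S <- matrix(0 + 0i, m, 2^n)
    S[, 1] <- 1 + 0i
    for (w in seq_len(n)) {
      half <- pi * segmat[w, idx] / 2
      c2 <- cos(half); s2 <- sin(half)
      p <- pairs[[w]]
      A0 <- S[, p$i0, drop = FALSE]; A1 <- S[, p$i1, drop = FALSE]
      S[, p$i0] <- c2 * A0 - s2 * A1
      S[, p$i1] <- s2 * A0 + c2 * A1
    }
    for (gate in circuit$gates) {
      if (gate$kind == "RX") {
        p <- pairs[[gate$wire]]
        c2 <- cos(gate$angle / 2)
        s2 <- complex(real = 0, imaginary = -sin(gate$angle / 2))
        A0 <- S[, p$i0, drop = FALSE]; A1 <- S[, p$i1, drop = FALSE]
        S[, p$i0] <- c2 * A0 + s2 * A1
        S[, p$i1] <- s2 * A0 + c2 * A1
      } else {
        S <- S[, cnot_permutation(n, gate$control, gate$target), drop = FALSE]
      }
    }
    prob <- Mod(S)^2
    for (w in seq_len(n)) {
      out[w, idx] <- 2 * rowSums(prob[, pairs[[w]]$i0, drop = FALSE]) - rowSums(prob)
    }
  }
  out
}

#' @export
encode_segments.quantum_circuit <- function(key, segmat, ...) {
  batch_quantum_encode(segmat, key)
}
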