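## Independent oracles used to pin expected values. These deliberately take
## the slow, direct route (dense matrices, exhaustive enumeration) and share
## no code with the package internals they check.

## Dense 2^n x 2^n gate embedding: kron(I, G, I) with wire 1 as the most
## significant basis bit.
oracle_kron_gate <- function(n, wire, G) {
  U <- 1
  for (w in seq_len(n)) U <- kronecker(U, if (w == wire) G else diag(2))
  U
}

oracle_cnot_dense <- function(n, control, target) {
  N <- 2^n
  U <- matrix(0, N, N)
  for (k in 0:(N - 1)) {
    cb <- bitwAnd(bitwShiftR(k, n - control), 1L)
    kp <- if (cb == 1L) bitwXor(k, bitwShiftL(1L, n - target)) else k
    U[kp + 1, k + 1] <- 1
  }
  U
}

oracle_ry <- function(phi) matrix(c(cos(phi / 2), sin(phi / 2),
                                    -sin(phi / 2), cos(phi / 2)), 2, 2)
oracle_rx <- function(phi) matrix(c(cos(phi / 2), -1i * sin(phi / 2),
                                    -1i * sin(phi / 2), cos(phi / 2)), 2, 2)

## Full-circuit encoder as an explicit product of dense unitaries applied
## to |0...0>, with per-wire <Z> from marginal probabilities.
oracle_quantum_encode <- function(seg, circ) {
  n <- circ$n_wires
  U <- diag(2^n)
  for (w in seq_len(n)) U <- oracle_kron_gate(n, w, oracle_ry(pi * seg[w])) %*% U
  for (g in circ$gates) {
    G <- if (g$kind == "RX") oracle_kron_gate(n, g$wire, oracle_rx(g$angle))
         else oracle_cnot_dense(n, g$control, g$target)
    U <- G %*% U
  }
  psi <- U[, 1]
  vapply(seq_len(n), function(w) {
    signs <- 1 - 2 * bitwAnd(bitwShiftR(0:(2^n - 1), n - w), 1L)
    sum(signs * Mod(psi)^2)
  }, numeric(1))
}

## Exhaustive pair-counting AUROC: fraction of label-discordant pairs
## ranked correctly, ties counted half.
oracle_auroc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

## Closed-form MI of a bivariate Gaussian with correlation rho, in nats.
gaussian_mi <- function(rho) -0.5 * log(1 - rho^2)

make_tiny_cohort <- function(n = 60, F = 6, T = 8, seed = 1, ...) {
  generate_cohort(cohort_config(
    n_examples = n, F = F, T = T, seed = seed,
    latent_attrs = list(list(name = "sex", n_classes = 2, effect_size = 1)), ...))
}
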