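test_that("init_state prepares |0...0> with unit norm", {
  expect_equal(init_state(1), c(1 + 0i, 0))
  expect_equal(init_state(2), c(1 + 0i, 0, 0, 0))
  s4 <- init_state(4)
  expect_length(s4, 16)
  expect_equal(sum(Mod(s4)^2), 1)
  expect_error(init_state(0), class = "enctsf_validation_error")
})

test_that("single-qubit gate identities hold exactly", {
  s0 <- init_state(1)
  expect_equal(apply_ry(s0, 1, 0), s0)                         # RY(0) = I
  expect_equal(apply_ry(s0, 1, pi), c(0 + 0i, 1 + 0i))         # RY(pi)|0> = |1>
  expect_equal(apply_ry(s0, 1, pi / 2), complex(real = c(sqrt(2) / 2, sqrt(2) / 2)))
  expect_equal(apply_rx(s0, 1, 0), s0)                         # RX(0) = I
  expect_equal(apply_rx(s0, 1, pi), c(0 + 0i, 0 - 1i))         # RX(pi)|0> = -i|1>
  expect_equal(apply_rx(s0, 1, pi / 2),
               c(complex(real = cos(pi / 4)), complex(imaginary = -sin(pi / 4))))
  expect_error(apply_ry(s0, 2, 1), class = "enctsf_index_error")
})

test_that("CNOT implements the truth table and the superposition case", {
  ket <- function(bits, n = 2) { s <- complex(2^n); s[bits + 1] <- 1; s }
  expect_equal(apply_cnot(ket(2L), 1, 2), ket(3L))  # |10> -> |11>
  expect_equal(apply_cnot(ket(0L), 1, 2), ket(0L))  # |00> -> |00>
  expect_equal(apply_cnot(ket(1L), 1, 2), ket(1L))  # |01> -> |01>
  expect_equal(apply_cnot(ket(3L), 1, 2), ket(2L))  # |11> -> |10>
  # a|00> + b|01> + c|10> + d|11>  ->  a|00> + b|01> + d|10> + c|11>
  abcd <- complex(real = c(0.1, 0.2, 0.3, 0.4), imaginary = c(0, 0.5, -0.2, 0.1))
  abcd <- abcd / sqrt(sum(Mod(abcd)^2))
  expect_equal(apply_cnot(abcd, 1, 2), abcd[c(1, 2, 4, 3)])
  expect_error(apply_cnot(abcd, 1, 1), class = "enctsf_validation_error")
})

test_that("Pauli-Z expectation reads P(0) - P(1) on the designated wire", {
  expect_equal(measure_z(init_state(1), 1), 1)
  expect_equal(measure_z(apply_ry(init_state(1), 1, pi), 1), -1)
  plus <- complex(real = c(1, 1)) / sqrt(2)
  expect_equal(measure_z(plus, 1), 0)
  # marginalization: wire 2 of |10> is still |0>
  s <- apply_ry(init_state(2), 1, pi)
  expect_equal(measure_z(s, 1), -1)
  expect_equal(measure_z(s, 2), 1)
})

test_that("random circuits have the stated layout and are seed-deterministic", {
  circ <- build_random_circuit(4, layers = 2, seed = 42)
  kinds <- vapply(circ$gates, `[[`, "", "kind")
  expect_equal(sum(kinds == "RX"), 8)
  expect_equal(sum(kinds == "CNOT"), 6)
  # ladder order within each layer: controls 1, 2, 3
  cn <- Filter(function(g) g$kind == "CNOT", circ$gates)
  expect_equal(vapply(cn, `[[`, 0L, "control"), c(1L, 2L, 3L, 1L, 2L, 3L))
  expect_equal(vapply(cn, `[[`, 0L, "target"), c(2L, 3L, 4L, 2L, 3L, 4L))
  angles <- function(c) vapply(Filter(function(g) g$kind == "RX", c$gates), `[[`, 0, "angle")
  expect_identical(angles(build_random_circuit(4, 2, seed = 7)),
                   angles(build_random_circuit(4, 2, seed = 7)))
  expect_false(identical(angles(build_random_circuit(4, 2, seed = 7)),
                         angles(build_random_circuit(4, 2, seed = 8))))
  expect_true(all(angles(circ) >= 0 & angles(circ) < 2 * pi))
  expect_error(build_random_circuit(1, 2, seed = 1), class = "enctsf_validation_error")
})

test_that("quantum encoding matches the dense-unitary oracle on random cases", {
  set.seed(10)
  for (trial in 1:30) {
    n <- sample(2:4, 1)
    circ <- build_random_circuit(n, layers = sample(1:3, 1), seed = 100 + trial)
    seg <- runif(n)
    expect_equal(quantum_encode_segment(seg, circ), oracle_quantum_encode(seg, circ),
                 tolerance = 1e-10)
  }
})

test_that("batch and single-segment quantum paths agree bit-for-bit in value", {
  circ <- build_random_circuit(4, 2, seed = 42)
  set.seed(4)
  segs <- matrix(runif(4 * 50), 4)
  batch <- encode_segments(circ, segs)
  single <- vapply(seq_len(50), function(j) quantum_encode_segment(segs[, j], circ),
                   numeric(4))
  expect_equal(batch, single, tolerance = 1e-12)
})

test_that("degenerate circuits give the analytic limits", {
  circ <- build_random_circuit(4, 1, seed = 1)
  # all RX angles zero, keep the CNOTs: CNOT on product RY states leaves
  # each wire's marginal unchanged only when controls are classical, so
  # drop all gates for the clean closed form
  empty <- circ; empty$gates <- list()
  expect_equal(quantum_encode_segment(rep(0, 4), empty), rep(1, 4))
  expect_equal(quantum_encode_segment(rep(1, 4), empty), rep(-1, 4))
  grid <- seq(0, 1, length.out = 21)
  for (v in grid) {
    expect_equal(quantum_encode_segment(rep(v, 4), empty), rep(cos(pi * v), 4),
                 tolerance = 1e-12)
  }
  # zero-angle RX gates are identities: only CNOTs act
  zero_rx <- circ
  zero_rx$gates <- lapply(zero_rx$gates, function(g) { if (g$kind == "RX") g$angle <- 0; g })
  expect_equal(quantum_encode_segment(rep(0, 4), zero_rx), rep(1, 4))
})

test_that("unitarity and boundedness hold across many random circuits", {
  set.seed(5)
  for (trial in 1:200) {
    n <- sample(2:4, 1)
    circ <- build_random_circuit(n, sample(1:3, 1), seed = 500 + trial)
    seg <- runif(n)
    state <- init_state(n)
    for (w in seq_len(n)) {
      state <- apply_ry(state, w, pi * seg[w])
      expect_lt(abs(sum(Mod(state)^2) - 1), 1e-12)
    }
    for (g in circ$gates) {
      state <- if (g$kind == "RX") apply_rx(state, g$wire, g$angle)
               else apply_cnot(state, g$control, g$target)
      expect_lt(abs(sum(Mod(state)^2) - 1), 1e-12)
    }
    e <- quantum_encode_segment(seg, circ)
    expect_true(all(e >= -1 - 1e-12 & e <= 1 + 1e-12))
  }
})

test_that("per-wire measurement is many-to-one: distinct states collide", {
  # |00> + |11> (Bell) and |00> + |10> style states both give <Z> = (0, 0)
  bell <- complex(real = c(1, 0, 0, 1)) / sqrt(2)
  prod_state <- kronecker(complex(real = c(1, 1)) / sqrt(2),
                          complex(real = c(1, 1)) / sqrt(2))
  expect_false(isTRUE(all.equal(bell, prod_state)))
  z <- function(s) c(measure_z(s, 1), measure_z(s, 2))
  expect_equal(z(bell), c(0, 0), tolerance = 1e-12)
  expect_equal(z(prod_state), c(0, 0), tolerance = 1e-12)
})

test_that("quantum key files round-trip including frozen scaling statistics", {
  circ <- build_random_circuit(4, 2, seed = 13, key_id = "qkey")
  circ$scaling <- list(min = c(f1 = -1, f2 = 0), max = c(f1 = 2, f2 = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_key(circ, path)
  back <- read_key(path)
  expect_equal(back$gates, circ$gates)
  expect_equal(back$scaling, circ$scaling)
  expect_identical(back$key_id, "qkey")
  set.seed(1); seg <- runif(4)
  expect_identical(quantum_encode_segment(seg, back), quantum_encode_segment(seg, circ))
})
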