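test_that("register initialization puts all amplitude on |00...0>", {
  s1 <- init_state(1)
  expect_equal(s1$amplitudes, c(1 + 0i, 0i))
  s5 <- init_state(5)
  expect_length(s5$amplitudes, 32L)
  expect_equal(Mod(s5$amplitudes)^2, c(1, rep(0, 31)))
  expect_equal(sum(Mod(s5$amplitudes)^2), 1)
  expect_error(init_state(0), "between", class = "qlung_validation_error")
  expect_error(init_state(13), "between", class = "qlung_validation_error")
})

test_that("gate matrices are unitary and match their definitions", {
  gates <- list(hadamard(), phase_gate(), rotation_y(0.37), rotation_z(-1.2))
  for (g in gates) {
    expect_lt(max(Mod(g$matrix %*% Conj(t(g$matrix)) - diag(2))), 1e-12)
  }
  expect_equal(hadamard()$matrix,
               matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2) + 0i)
  expect_equal(phase_gate()$matrix, matrix(c(1, 0, 0, 1i), 2, 2))
  expect_equal(rotation_y(0)$matrix, diag(2) + 0i)
})

test_that("Hadamard creates the equal superposition and squares to identity", {
  s <- apply_gate(init_state(1), hadamard(), 0)
  expect_equal(s$amplitudes, complex(real = c(1, 1) / sqrt(2)), tolerance = 1e-12)
  expect_equal(Re(s$amplitudes), c(0.70710678, 0.70710678), tolerance = 1e-8)

  # |1> -> (|0> - |1>)/sqrt(2)
  one <- init_state(1); one$amplitudes <- c(0i, 1 + 0i)
  s1 <- apply_gate(one, hadamard(), 0)
  expect_equal(s1$amplitudes, complex(real = c(1, -1) / sqrt(2)), tolerance = 1e-12)

  rnd <- init_state(1)
  rnd$amplitudes <- complex(real = c(0.6, 0.48), imaginary = c(0, 0.64))
  back <- apply_gate(apply_gate(rnd, hadamard(), 0), hadamard(), 0)
  expect_lt(max(Mod(back$amplitudes - rnd$amplitudes)), 1e-12)
})

test_that("the phase gate multiplies |1> by i and has order four", {
  s0 <- apply_gate(init_state(1), phase_gate(), 0)
  expect_equal(s0$amplitudes, c(1 + 0i, 0i))

  one <- init_state(1); one$amplitudes <- c(0i, 1 + 0i)
  s1 <- apply_gate(one, phase_gate(), 0)
  expect_equal(s1$amplitudes[2], 1i)

  s <- apply_gate(init_state(1), hadamard(), 0)
  four <- s
  for (k in 1:4) four <- apply_gate(four, phase_gate(), 0)
  expect_lt(max(Mod(four$amplitudes - s$amplitudes)), 1e-12)
})

test_that("RY rotations reproduce the cosine expectation law", {
  expect_equal(rotation_y(0)$matrix, diag(2) + 0i)
  s_pi <- apply_gate(init_state(1), rotation_y(pi), 0)
  expect_equal(Mod(s_pi$amplitudes)^2, c(0, 1), tolerance = 1e-12)
  for (th in c(0, pi / 4, pi / 2)) {
    s <- apply_gate(init_state(1), rotation_y(th), 0)
    expect_equal(expectation_z(s, 0), cos(th), tolerance = 1e-12)
  }
})

test_that("gate application matches the dense-matrix oracle for small registers", {
  for (n in 2:4) {
    for (seed in 1:3) {
      circ <- random_circuit(n, len = 12L, seed = 100 * n + seed)
      state <- init_state(n)
      dense <- state$amplitudes
      for (step in circ) {
        state <- apply_gate(state, step$gate, step$qubits)
        dense <- oracle_apply_dense(dense, step$gate, step$qubits, n)
      }
      expect_lt(max(Mod(state$amplitudes - dense)), 1e-10)
    }
  }
})

test_that("CNOT leaves inactive controls alone and builds Bell states", {
  s <- apply_gate(init_state(2), cnot_gate(), c(0, 1))
  expect_equal(s$amplitudes, c(1 + 0i, 0i, 0i, 0i))

  bell <- apply_gate(apply_gate(init_state(2), hadamard(), 0),
                     cnot_gate(), c(0, 1))
  expect_equal(bell$amplitudes,
               complex(real = c(1, 0, 0, 1) / sqrt(2)), tolerance = 1e-12)
  expect_equal(expectation_z(bell, 0), 0, tolerance = 1e-12)
  expect_equal(expectation_z(bell, 1), 0, tolerance = 1e-12)

  expect_error(apply_gate(init_state(2), cnot_gate(), c(1, 1)),
               "distinct", class = "qlung_validation_error")
  expect_error(apply_gate(init_state(2), hadamard(), 5),
               "range", class = "qlung_validation_error")
})

test_that("norm is conserved through long random circuits", {
  for (seed in 1:100) {
    circ <- random_circuit(5L, len = 50L, seed = seed)
    state <- init_state(5)
    for (step in circ) state <- apply_gate(state, step$gate, step$qubits)
    expect_lt(abs(sum(Mod(state$amplitudes)^2) - 1), 1e-9)
  }
})

test_that("expectation_z follows the spin-up sign convention", {
  expect_equal(expectation_z(init_state(3), 1), 1)
  h <- apply_gate(init_state(1), hadamard(), 0)
  expect_equal(expectation_z(h, 0), 0, tolerance = 1e-12)
})

test_that("parameter-shift gradients equal closed forms and finite differences", {
  f <- function(a) expectation_z(apply_gate(init_state(1), rotation_y(a[1]), 0), 0)
  expect_equal(parameter_shift_gradient(f, pi / 2, 1), -1, tolerance = 1e-12)
  expect_equal(parameter_shift_gradient(f, 0, 1), 0, tolerance = 1e-12)
  expect_error(parameter_shift_gradient(f, 1, 3), "range",
               class = "qlung_validation_error")

  # random parameterized 5-qubit circuits vs central finite differences
  run <- function(angles) {
    s <- init_state(5)
    for (q in 0:4) s <- apply_gate(s, hadamard(), q)
    for (j in seq_along(angles)) {
      q <- (j - 1) %% 5
      s <- if (j %% 2 == 0) apply_gate(s, rotation_z(angles[j]), q)
      else apply_gate(s, rotation_y(angles[j]), q)
      if (q < 4) s <- apply_gate(s, cnot_gate(), c(q, q + 1))
    }
    expectation_z(s, 2)
  }
  for (seed in 1:5) {
    angles <- withr::with_seed(seed, runif(6, -pi, pi))
    for (j in seq_along(angles)) {
      expect_equal(parameter_shift_gradient(run, angles, j),
                   fd_gradient(run, angles, j), tolerance = 1e-5)
    }
  }
})

test_that("sampled measurements follow the amplitude distribution", {
  bell <- apply_gate(apply_gate(init_state(2), hadamard(), 0),
                     cnot_gate(), c(0, 1))
  draws <- withr::with_seed(1, sample_measurements(bell, shots = 4000))
  expect_setequal(unique(draws), c(0L, 3L))
  expect_equal(mean(draws == 0L), 0.5, tolerance = 0.05)
})

test_that("circuits survive a JSON round trip", {
  circ <- list(
    list(gate = hadamard(), qubits = 0L),
    list(gate = rotation_y(0.7), qubits = 1L),
    list(gate = phase_gate(), qubits = 2L),
    list(gate = cnot_gate(), qubits = c(0L, 2L))
  )
  p <- tempfile(fileext = ".json")
  circuit_to_json(circ, p)
  circ2 <- circuit_from_json(p)
  s1 <- run_circuit(circ, 3)
  s2 <- run_circuit(circ2, 3)
  expect_equal(s1$amplitudes, s2$amplitudes)
})
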