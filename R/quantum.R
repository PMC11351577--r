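#' Initialize a qubit register in |00...0>
#'
#' The simulator is a dense statevector over the 2^n computational basis
#' states. Qubit ordering is little-endian throughout: qubit 0 is the least
#' significant bit of the basis index.
#'
#' @param n_qubits Register size, 1--12.
#' @return A `state_vector`: complex `amplitudes` of length `2^n_qubits` and
#'   `n_qubits`.
#' @export
init_state <- function(n_qubits) {
  n_qubits <- as.integer(n_qubits)
  if (is.na(n_qubits) || n_qubits < 1L || n_qubits > 12L) {
    abort_validation("n_qubits must be between 1 and 12")
  }
  amp <- complex(real = c(1, rep(0, 2^n_qubits - 1L)))
  structure(list(amplitudes = amp, n_qubits = n_qubits), class = "state_vector")
}

#' @export
print.state_vector <- function(x, ...) {
  cat(sprintf("<state_vector> %d qubits (%d amplitudes), norm %.6f\n",
              x$n_qubits, length(x$amplitudes), sqrt(sum(Mod(x$amplitudes)^2))))
  invisible(x)
}

new_gate <- function(name, matrix = NULL, parameter = NULL, cnot = FALSE) {
  if (!cnot) {
    u <- matrix %*% Conj(t(matrix))
    if (max(Mod(u - diag(2))) > 1e-12) {
      abort_validation(sprintf("gate '%s' matrix is not unitary", name))
    }
  }
  structure(list(name = name, matrix = matrix, parameter = parameter,
                 cnot = cnot), class = "quantum_gate")
}

#' Standard gate constructors
#'
#' `hadamard()` maps |0> to (|0> + |1>)/sqrt(2) and |1> to (|0> - |1>)/sqrt(2);
#' `phase_gate()` is the S gate `diag(1, i)`, multiplying the |1> amplitude
#' by i; `rotation_y()`/`rotation_z()` are the standard RY/RZ rotations
#' `exp(-i theta Y/2)` / `exp(-i theta Z/2)`; `cnot_gate()` is the
#' controlled-NOT marker applied with a (control, target) pair.
#'
#' @param theta Rotation angle in radians.
#' @return A `quantum_gate`.
#' @export
hadamard <- function() {
  new_gate("H", matrix(complex(real = c(1, 1, 1, -1)), 2, 2) / sqrt(2))
}

#' @rdname hadamard
#' @export
phase_gate <- function() {
  new_gate("S", matrix(c(1 + 0i, 0i, 0i, 1i), 2, 2))
}

#' @rdname hadamard
#' @export
rotation_y <- function(theta) {
  if (!is.finite(theta)) abort_validation("theta must be finite")
  c2 <- cos(theta / 2); s2 <- sin(theta / 2)
  new_gate("RY", matrix(complex(real = c(c2, s2, -s2, c2)), 2, 2),
           parameter = theta)
}

#' @rdname hadamard
#' @export
rotation_z <- function(theta) {
  if (!is.finite(theta)) abort_validation("theta must be finite")
  new_gate("RZ", diag(exp(complex(imaginary = c(-theta / 2, theta / 2)))),
           parameter = theta)
}

#' @rdname hadamard
#' @export
cnot_gate <- function() new_gate("CNOT", cnot = TRUE)

#' Apply a gate to a statevector
#'
#' Tensor-structured update touching only the addressed qubit(s); no full
#' 2^n x 2^n matrix is formed.
#'
#' @param state A `state_vector`.
#' @param gate A `quantum_gate`.
#' @param qubits Zero-based qubit index for single-qubit gates, or a
#'   `c(control, target)` pair for CNOT.
#' @return The updated `state_vector`.
#' @export
apply_gate <- function(state, gate, qubits) {
  stopifnot(inherits(state, "state_vector"), inherits(gate, "quantum_gate"))
  n <- state$n_qubits
  qubits <- as.integer(qubits)
  if (any(is.na(qubits)) || any(qubits < 0L) || any(qubits >= n)) {
    abort_validation(sprintf("qubit index out of range [0, %d)", n))
  }
  amp <- state$amplitudes
  if (gate$cnot) {
    if (length(qubits) != 2L || qubits[1] == qubits[2]) {
      abort_validation("CNOT needs distinct (control, target) indices")
    }
    cbit <- bitwAnd(0:(2^n - 1L), bitwShiftL(1L, qubits[1])) > 0L
    tbit0 <- bitwAnd(0:(2^n - 1L), bitwShiftL(1L, qubits[2])) == 0L
    i0 <- which(cbit & tbit0)            # control 1, target 0 (1-based)
    i1 <- i0 + 2L^qubits[2]
    tmp <- amp[i0]; amp[i0] <- amp[i1]; amp[i1] <- tmp
  } else {
    if (length(qubits) != 1L) abort_validation("single-qubit gate takes one index")
    q <- qubits[1]
    i0 <- which(bitwAnd(0:(2^n - 1L), bitwShiftL(1L, q)) == 0L)  # 1-based
    i1 <- i0 + 2L^q
    a0 <- amp[i0]; a1 <- amp[i1]
    m <- gate$matrix
    amp[i0] <- m[1, 1] * a0 + m[1, 2] * a1
    amp[i1] <- m[2, 1] * a0 + m[2, 2] * a1
  }
  state$amplitudes <- amp
  state
}

#' Pauli-Z expectation of one qubit
#'
#' Deterministic expectation over basis probabilities with the spin-up
#' convention |0> -> +1, |1> -> -1 (no sampled collapse).
#'
#' @param state A `state_vector`.
#' @param qubit Zero-based qubit index.
#' @return A real number in `[-1, 1]`.
#' @export
expectation_z <- function(state, qubit) {
  stopifnot(inherits(state, "state_vector"))
  qubit <- as.integer(qubit)
  if (is.na(qubit) || qubit < 0L || qubit >= state$n_qubits) {
    abort_validation("qubit index out of range")
  }
  probs <- Mod(state$amplitudes)^2
  sign <- ifelse(bitwAnd(0:(length(probs) - 1L), bitwShiftL(1L, qubit)) == 0L,
                 1, -1)
  sum(probs * sign)
}

#' Sample computational-basis measurements
#'
#' Demonstration-only sampling mode; training always uses the deterministic
#' [expectation_z()].
#'
#' @param state A `state_vector`.
#' @param shots Number of samples.
#' @return Integer vector of sampled basis indices (0-based).
#' @export
sample_measurements <- function(state, shots = 1024L) {
  probs <- Mod(state$amplitudes)^2
  sample.int(length(probs), size = shots, replace = TRUE,
             prob = probs / sum(probs)) - 1L
}

#' Parameter-shift gradient of a circuit observable
#'
#' For an observable `f(angles)` whose addressed parameter enters only
#' through RY/RZ gates, the exact derivative is
#' `(f(theta + pi/2) - f(theta - pi/2)) / 2`.
#'
#' @param runner Function mapping an angle vector to a scalar observable.
#' @param angles Parameter vector.
#' @param index Which parameter to differentiate (1-based).
#' @return The derivative, a real scalar.
#' @export
parameter_shift_gradient <- function(runner, angles, index) {
  index <- as.integer(index)
  if (is.na(index) || index < 1L || index > length(angles)) {
    abort_validation("parameter index out of range")
  }
  up <- angles; up[index] <- up[index] + pi / 2
  dn <- angles; dn[index] <- dn[index] - pi / 2
  (runner(up) - runner(dn)) / 2
}

#' Serialize / deserialize a gate list
#'
#' A circuit is an ordered list of `list(gate, qubits)` steps; serialization
#' records gate names, target indices and parameter slots.
#'
#' @param circuit List of steps `list(gate = <quantum_gate>, qubits = <int>)`.
#' @param path JSON output path.
#' @return `circuit_to_json` returns `path` invisibly; `circuit_from_json`
#'   returns the reconstructed circuit list.
#' @export
circuit_to_json <- function(circuit, path) {
  steps <- map(circuit, function(s) {
    list(name = s$gate$name, qubits = as.integer(s$qubits),
         parameter = s$gate$parameter)
  })
  jsonlite::write_json(steps, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname circuit_to_json
#' @export
circuit_from_json <- function(path) {
  steps <- jsonlite::read_json(path, simplifyVector = FALSE)
  map(steps, function(s) {
    gate <- switch(s$name,
      H = hadamard(), S = phase_gate(), CNOT = cnot_gate(),
      RY = rotation_y(s$parameter), RZ = rotation_z(s$parameter),
      abort_validation(sprintf("unknown gate '%s' in circuit file", s$name)))
    list(gate = gate, qubits = as.integer(unlist(s$qubits)))
  })
}

#' Run a gate list on a fresh register
#'
#' @param circuit List of steps as in [circuit_to_json()].
#' @param n_qubits Register size.
#' @return Final `state_vector`.
#' @export
run_circuit <- function(circuit, n_qubits) {
  state <- init_state(n_qubits)
  for (s in circuit) state <- apply_gate(state, s$gate, s$qubits)
  state
}
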