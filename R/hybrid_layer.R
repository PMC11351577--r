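#' Specify the variational quantum circuit layer
#'
#' The trainable 5-in/5-out layer: a Hadamard wall, RY angle embedding (one
#' feature per qubit), `n_var_layers` variational blocks (one RY angle per
#' qubit followed by a linear CNOT chain), and a Pauli-Z expectation readout
#' per qubit.
#'
#' @param n_qubits Number of qubits (default 5, one per quantum feature).
#' @param n_var_layers Number of variational blocks (default 2; 0 gives a
#'   fixed embed-then-measure layer).
#' @param embedding Feature embedding family; only `"angle_ry"`.
#' @param entangler `"chain_cnot"` (CNOT chain 0->1, 1->2, ...) or `"none"`.
#' @param params Variational angles, length `n_qubits * n_var_layers`
#'   (default all zero).
#' @param scaler Optional `angle_scaler` from [fit_scaler()]; when present,
#'   inputs to [quantum_forward()] are raw quantum features and are scaled to
#'   angles internally, otherwise inputs are taken as angles.
#' @return A `circuit_spec`.
#' @export
circuit_spec <- function(n_qubits = 5L, n_var_layers = 2L,
                         embedding = "angle_ry", entangler = "chain_cnot",
                         params = NULL, scaler = NULL) {
  n_qubits <- as.integer(n_qubits); n_var_layers <- as.integer(n_var_layers)
  if (!embedding %in% "angle_ry") abort_validation("unknown embedding family")
  if (!entangler %in% c("chain_cnot", "none")) {
    abort_validation("entangler must be 'chain_cnot' or 'none'")
  }
  n_params <- n_qubits * n_var_layers
  if (is.null(params)) params <- rep(0, n_params)
  if (length(params) != n_params) {
    abort_validation(sprintf("params must have length %d (n_qubits * n_var_layers), got %d",
                             n_params, length(params)))
  }
  structure(
    list(n_qubits = n_qubits, n_var_layers = n_var_layers,
         embedding = embedding, entangler = entangler,
         params = as.numeric(params), scaler = scaler),
    class = "circuit_spec"
  )
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf("<circuit_spec> %d qubits, %d variational layer(s), %d parameter(s), entangler %s\n",
              x$n_qubits, x$n_var_layers, length(x$params), x$entangler))
  invisible(x)
}

#' Fit the per-feature angle scaler
#'
#' Records per-feature training min/max; the transform maps the training
#' range linearly onto `[0, pi]`, clamps out-of-range inference values, and
#' maps degenerate (constant) features to `pi/2`.
#'
#' @param q Training quantum features: matrix or tibble with `q1 ... qk`
#'   columns; at least two rows.
#' @return An `angle_scaler`.
#' @export
fit_scaler <- function(q) {
  m <- quantum_feature_matrix(q)
  if (nrow(m) < 2L) abort_validation("angle scaler needs at least 2 training rows")
  structure(list(min = apply(m, 2L, min), max = apply(m, 2L, max)),
            class = "angle_scaler")
}

#' Map quantum features to embedding angles
#'
#' @param scaler An `angle_scaler`.
#' @param q Feature vector, matrix or tibble.
#' @return Angles in `[0, pi]`, same shape as the numeric input.
#' @export
scale_angles <- function(scaler, q) {
  stopifnot(inherits(scaler, "angle_scaler"))
  vec <- !is.matrix(q) && !is.data.frame(q)
  m <- if (vec) matrix(as.numeric(q), nrow = 1L) else quantum_feature_matrix(q)
  if (ncol(m) != length(scaler$min)) {
    abort_validation("feature count does not match the fitted scaler")
  }
  rng <- scaler$max - scaler$min
  out <- m
  for (j in seq_len(ncol(m))) {
    if (rng[j] <= 0) {
      out[, j] <- pi / 2
    } else {
      v <- pmin(pmax(m[, j], scaler$min[j]), scaler$max[j])
      out[, j] <- pi * (v - scaler$min[j]) / rng[j]
    }
  }
  if (vec) as.numeric(out) else out
}

quantum_feature_matrix <- function(q) {
  if (is.data.frame(q)) {
    qcols <- grep("^q[0-9]+$", names(q), value = TRUE)
    as.matrix(q[, qcols])
  } else {
    as.matrix(q)
  }
}

# ---- batched statevector engine ------------------------------------------
# Amplitudes held as a 2^n x B complex matrix; every helper touches only the
# addressed qubit's index pairs. Little-endian ordering as in apply_gate().

bpairs <- function(n, q) {
  i0 <- which(bitwAnd(0:(2^n - 1L), bitwShiftL(1L, q)) == 0L)
  list(i0 = i0, i1 = i0 + 2L^q)
}

bapply_mat <- function(A, n, q, m) {
  p <- bpairs(n, q)
  a0 <- A[p$i0, , drop = FALSE]; a1 <- A[p$i1, , drop = FALSE]
  A[p$i0, ] <- m[1, 1] * a0 + m[1, 2] * a1
  A[p$i1, ] <- m[2, 1] * a0 + m[2, 2] * a1
  A
}

# RY with one angle per batch column.
bapply_ry_batch <- function(A, n, q, thetas) {
  p <- bpairs(n, q)
  c2 <- rep(cos(thetas / 2), each = length(p$i0))
  s2 <- rep(sin(thetas / 2), each = length(p$i0))
  a0 <- A[p$i0, , drop = FALSE]; a1 <- A[p$i1, , drop = FALSE]
  A[p$i0, ] <- c2 * a0 - s2 * a1
  A[p$i1, ] <- s2 * a0 + c2 * a1
  A
}

bapply_cnot <- function(A, n, ctrl, tgt) {
  cbit <- bitwAnd(0:(2^n - 1L), bitwShiftL(1L, ctrl)) > 0L
  t0 <- bitwAnd(0:(2^n - 1L), bitwShiftL(1L, tgt)) == 0L
  i0 <- which(cbit & t0); i1 <- i0 + 2L^tgt
  tmp <- A[i0, , drop = FALSE]
  A[i0, ] <- A[i1, , drop = FALSE]
  A[i1, ] <- tmp
  A
}

bexp_z <- function(A, n, q) {
  sign <- ifelse(bitwAnd(0:(2^n - 1L), bitwShiftL(1L, q)) == 0L, 1, -1)
  colSums(Mod(A)^2 * sign)
}

# Core batched forward: angles is B x n_qubits (already scaled), params the
# flat variational angle vector. Returns B x n_qubits expectation matrix.
qforward_angles <- function(spec, angles, params = spec$params) {
  n <- spec$n_qubits
  B <- nrow(angles)
  A <- matrix(0i, 2^n, B)
  A[1L, ] <- 1 + 0i
  h <- matrix(complex(real = c(1, 1, 1, -1)), 2, 2) / sqrt(2)
  for (q in 0:(n - 1L)) A <- bapply_mat(A, n, q, h)
  for (q in 0:(n - 1L)) A <- bapply_ry_batch(A, n, q, angles[, q + 1L])
  if (spec$n_var_layers > 0L) {
    pm <- matrix(params, nrow = spec$n_var_layers, byrow = TRUE)
    for (l in seq_len(spec$n_var_layers)) {
      for (q in 0:(n - 1L)) {
        th <- pm[l, q + 1L]
        m <- matrix(complex(real = c(cos(th / 2), sin(th / 2),
                                     -sin(th / 2), cos(th / 2))), 2, 2)
        A <- bapply_mat(A, n, q, m)
      }
      if (spec$entangler == "chain_cnot" && n > 1L) {
        for (q in 0:(n - 2L)) A <- bapply_cnot(A, n, q, q + 1L)
      }
    }
  }
  out <- vapply(0:(n - 1L), function(q) bexp_z(A, n, q), numeric(B))
  matrix(out, nrow = B)
}

#' Forward pass of the variational quantum layer
#'
#' @param spec A `circuit_spec`.
#' @param q One quantum feature vector (length `n_qubits`), a matrix or a
#'   tibble of features (rows = samples). Raw features are scaled to angles
#'   through `spec$scaler` when one is attached.
#' @param params Optional parameter override (defaults to `spec$params`).
#' @return Per-qubit Z expectations in `[-1, 1]`: a numeric vector for a
#'   vector input, otherwise a samples x n_qubits matrix.
#' @export
quantum_forward <- function(spec, q, params = spec$params) {
  stopifnot(inherits(spec, "circuit_spec"))
  vec <- !is.matrix(q) && !is.data.frame(q)
  m <- if (vec) matrix(as.numeric(q), nrow = 1L) else quantum_feature_matrix(q)
  if (ncol(m) != spec$n_qubits) {
    abort_validation(sprintf("expected %d features per sample, got %d",
                             spec$n_qubits, ncol(m)))
  }
  angles <- if (is.null(spec$scaler)) m else scale_angles(spec$scaler, m)
  z <- qforward_angles(spec, angles, params)
  if (vec) as.numeric(z) else z
}

#' Parameter-shift Jacobian of the quantum layer
#'
#' One parameter-shift pair of circuit evaluations per variational parameter;
#' exact for RY parameters.
#'
#' @inheritParams quantum_forward
#' @return For a single sample, an `n_qubits x n_params` matrix of
#'   d<Z_k>/d theta_j; for batched input, an array
#'   `[samples, n_qubits, n_params]`.
#' @export
quantum_gradients <- function(spec, q, params = spec$params) {
  stopifnot(inherits(spec, "circuit_spec"))
  vec <- !is.matrix(q) && !is.data.frame(q)
  m <- if (vec) matrix(as.numeric(q), nrow = 1L) else quantum_feature_matrix(q)
  angles <- if (is.null(spec$scaler)) m else scale_angles(spec$scaler, m)
  n_par <- length(params)
  out <- array(0, c(nrow(m), spec$n_qubits, max(n_par, 0L)))
  for (j in seq_len(n_par)) {
    up <- params; up[j] <- up[j] + pi / 2
    dn <- params; dn[j] <- dn[j] - pi / 2
    out[, , j] <- (qforward_angles(spec, angles, up) -
                     qforward_angles(spec, angles, dn)) / 2
  }
  if (vec) {
    if (n_par == 0L) matrix(0, spec$n_qubits, 0L)
    else matrix(out[1L, , ], nrow = spec$n_qubits, ncol = n_par)
  } else {
    out
  }
}
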