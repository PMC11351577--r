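# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: loops instead of im2col, dense Kronecker matrices
# instead of index-pair updates, pairwise concordance instead of a threshold
# sweep.

# Brute-force CNN forward: per-layer loops on [h, w, c] arrays.
oracle_cnn_forward <- function(backbone, pixels, upto) {
  x <- array(pixels / 255, c(nrow(pixels), ncol(pixels), 1L))
  act <- function(z, a) switch(a, relu = pmax(z, 0),
                               sigmoid = 1 / (1 + exp(-z)), none = z)
  for (ly in backbone$layers) {
    if (ly$kind == "conv") {
      wb <- backbone$weights[[ly$name]]
      k <- ly$size
      oh <- dim(x)[1] - k + 1L; ow <- dim(x)[2] - k + 1L
      out <- array(0, c(oh, ow, ly$filters))
      for (f in seq_len(ly$filters)) {
        for (i in seq_len(oh)) for (j in seq_len(ow)) {
          s <- 0
          for (ci in seq_len(dim(x)[3])) for (dj in seq_len(k)) for (di in seq_len(k)) {
            wrow <- ((ci - 1L) * k + (dj - 1L)) * k + di
            s <- s + x[i + di - 1L, j + dj - 1L, ci] * wb$W[wrow, f]
          }
          out[i, j, f] <- s + wb$b[f]
        }
      }
      x <- act(out, ly$activation)
    } else if (ly$kind == "pool") {
      k <- ly$size
      oh <- dim(x)[1] %/% k; ow <- dim(x)[2] %/% k
      out <- array(0, c(oh, ow, dim(x)[3]))
      for (ci in seq_len(dim(x)[3])) for (i in seq_len(oh)) for (j in seq_len(ow)) {
        out[i, j, ci] <- max(x[(i - 1L) * k + seq_len(k),
                               (j - 1L) * k + seq_len(k), ci])
      }
      x <- out
    } else {
      wb <- backbone$weights[[ly$name]]
      h <- dim(x)[1]; w <- dim(x)[2]; nc <- dim(x)[3]
      v <- numeric(h * w * nc)
      for (ci in seq_len(nc)) for (j in seq_len(w)) for (i in seq_len(h)) {
        v[((ci - 1L) * w + (j - 1L)) * h + i] <- x[i, j, ci]
      }
      z <- as.numeric(v %*% wb$W) + wb$b
      x <- array(act(z, ly$activation), c(1L, 1L, ly$units))
    }
    if (ly$name == upto) return(as.vector(x))
  }
  as.vector(x)
}

# Dense full-register matrix of a gate (little-endian qubit 0 = LSB).
oracle_gate_matrix <- function(gate, qubits, n) {
  I2 <- diag(2)
  if (!gate$cnot) {
    mats <- rep(list(I2), n)
    mats[[qubits[1] + 1L]] <- gate$matrix
    # kron: last factor is most significant -> reverse order
    Reduce(kron_c, rev(mats))
  } else {
    dim_ <- 2^n
    M <- matrix(0 + 0i, dim_, dim_)
    for (j in 0:(dim_ - 1L)) {
      out <- if (bitwAnd(j, bitwShiftL(1L, qubits[1])) > 0L) {
        bitwXor(j, bitwShiftL(1L, qubits[2]))
      } else j
      M[out + 1L, j + 1L] <- 1
    }
    M
  }
}

kron_c <- function(a, b) kronecker(a, b)

oracle_apply_dense <- function(amplitudes, gate, qubits, n) {
  as.vector(oracle_gate_matrix(gate, qubits, n) %*% amplitudes)
}

# Central finite difference of a scalar function.
fd_gradient <- function(f, x, index, h = 1e-5) {
  up <- x; up[index] <- up[index] + h
  dn <- x; dn[index] <- dn[index] - h
  (f(up) - f(dn)) / (2 * h)
}

# Pairwise concordance (Wilcoxon) AUC.
oracle_concordance_auc <- function(truth, scores, positive = "malignant") {
  if (is.character(truth) || is.factor(truth)) {
    truth <- as.character(truth) == positive
  }
  truth <- as.logical(truth)
  sp <- scores[truth]; sn <- scores[!truth]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Random circuit builder shared by quantum-core tests: a seeded sequence of
# H/S/RY/RZ/CNOT steps on n qubits.
random_circuit <- function(n, len, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(len), function(i) {
      kind <- sample(c("H", "S", "RY", "RZ", "CNOT"), 1L)
      if (kind == "CNOT" && n > 1L) {
        qs <- sample(0:(n - 1L), 2L)
        list(gate = cnot_gate(), qubits = qs)
      } else {
        g <- switch(kind, H = hadamard(), S = phase_gate(),
                    RY = rotation_y(runif(1, -pi, pi)),
                    RZ = rotation_z(runif(1, -pi, pi)),
                    CNOT = hadamard())
        list(gate = g, qubits = sample(0:(n - 1L), 1L))
      }
    })
  })
}
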