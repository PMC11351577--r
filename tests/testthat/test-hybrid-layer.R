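test_that("the angle scaler maps the training range onto [0, pi]", {
  m <- cbind(q1 = c(0, 5, 10), q2 = c(2, 2, 2), q3 = c(-1, 0, 1),
             q4 = c(0, 1, 4), q5 = c(10, 20, 30))
  sc <- fit_scaler(m)
  a <- scale_angles(sc, m)
  expect_equal(a[, 1], c(0, pi / 2, pi))          # min -> 0, halfway -> pi/2, max -> pi
  expect_equal(a[, 2], rep(pi / 2, 3))            # degenerate feature
  expect_equal(scale_angles(sc, c(20, 2, 2, 5, 40))[c(1, 4, 5)],
               c(pi, pi, pi))                     # out-of-range clamped
  expect_error(fit_scaler(m[1, , drop = FALSE]), "2 training rows",
               class = "qlung_validation_error")
})

test_that("the default circuit measures zero expectations at the symmetric point", {
  # all scaled inputs 0 and all variational angles 0: per qubit H|0> stays
  # |+>, CNOT chain fixes |+...+>, so every <Z> vanishes -- dense oracle value
  spec <- circuit_spec()
  expect_equal(spec$n_qubits, 5L)
  expect_length(spec$params, 10L)
  z <- quantum_forward(spec, rep(0, 5))
  expect_equal(z, rep(0, 5), tolerance = 1e-10)

  withr::with_seed(3, {
    for (i in 1:10) {
      zr <- quantum_forward(circuit_spec(params = runif(10, -pi, pi)),
                            runif(5, 0, pi))
      expect_true(all(zr >= -1 - 1e-12 & zr <= 1 + 1e-12))
    }
  })
  expect_error(quantum_forward(spec, rep(0, 4)), "expected 5",
               class = "qlung_validation_error")
})

test_that("forward is bit-deterministic and factorizes without entanglers", {
  spec <- circuit_spec(params = seq(0.1, 1, by = 0.1))
  x <- c(0.3, 1.1, 2.2, 0.7, 3.0)
  expect_identical(quantum_forward(spec, x), quantum_forward(spec, x))

  # product-state check: with one layer and no CNOTs, permuting the layer's
  # parameters permutes the affected qubits' outputs only
  sp <- circuit_spec(n_var_layers = 1L, entangler = "none",
                     params = c(0.2, 0.4, 0.6, 0.8, 1.0))
  z1 <- quantum_forward(sp, x)
  perm <- c(2L, 1L, 3L, 5L, 4L)
  sp2 <- circuit_spec(n_var_layers = 1L, entangler = "none",
                      params = sp$params[perm])
  z2 <- quantum_forward(sp2, x[perm])
  expect_equal(z2, z1[perm], tolerance = 1e-12)

  # closed form for the isolated qubit: H then RY(x + theta) gives -sin(x+theta)
  expect_equal(z1, -sin(x + sp$params), tolerance = 1e-10)
})

test_that("an embed-then-measure layer matches the -sin closed form", {
  m <- withr::with_seed(5, matrix(runif(50, -2, 2), 10, 5))
  sc <- fit_scaler(m)
  spec <- circuit_spec(n_var_layers = 0L, scaler = sc)
  z <- quantum_forward(spec, m)
  expect_equal(z, -sin(scale_angles(sc, m)), tolerance = 1e-10)
})

test_that("layer Jacobians match closed forms and finite differences", {
  x <- c(0.3, 0.9, 1.4, 2.0, 2.6)

  empty <- quantum_gradients(circuit_spec(n_var_layers = 0L), x)
  expect_equal(dim(empty), c(5L, 0L))

  # isolated qubits, theta = 0: d<Z_i>/d theta_i = -cos(x_i), cross terms 0
  sp <- circuit_spec(n_var_layers = 1L, entangler = "none")
  jac <- quantum_gradients(sp, x)
  expect_equal(diag(jac), -cos(x), tolerance = 1e-10)
  expect_equal(jac - diag(diag(jac)), matrix(0, 5, 5), tolerance = 1e-10)

  spec <- circuit_spec(params = withr::with_seed(9, runif(10, -pi, pi)))
  jac2 <- quantum_gradients(spec, x)
  for (k in 1:5) {
    fk <- function(p) quantum_forward(spec, x, params = p)[k]
    for (j in 1:10) {
      expect_equal(jac2[k, j], fd_gradient(fk, spec$params, j),
                   tolerance = 1e-5)
    }
  }
})

test_that("the layer plus a linear readout learns a separable problem", {
  withr::with_seed(77, {
    n <- 40
    y <- rep(c(0, 1), each = n / 2)
    x <- matrix(runif(n * 5, 0, pi / 2), n, 5)
    x[y == 1, 1] <- x[y == 1, 1] + pi / 2  # feature 1 separates the classes
  })
  spec <- circuit_spec(params = rep(0.05, 10))
  w <- rep(0, 5); b <- 0
  lr <- 0.2
  for (step in 1:200) {
    z <- quantum_forward(spec, x)           # n x 5
    p <- 1 / (1 + exp(-(z %*% w + b)))
    d <- (p - y) / n                        # d loss / d logit
    gw <- t(z) %*% d
    gb <- sum(d)
    gz <- d %*% t(w)                        # n x 5
    jac <- quantum_gradients(spec, x)       # n x 5 x 10
    gtheta <- vapply(1:10, function(j) sum(gz * jac[, , j]), numeric(1))
    w <- w - lr * gw; b <- b - lr * gb
    spec$params <- spec$params - lr * gtheta
  }
  acc <- mean((quantum_forward(spec, x) %*% w + b > 0) == y)
  expect_gte(acc, 0.95)
})
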