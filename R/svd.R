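#' Fit an SVD feature compressor
#'
#' Compresses fused feature vectors to a small number of "quantum features"
#' (default five, one per qubit of the circuit downstream). The training
#' matrix is column-mean centered, its thin SVD taken, and the leading right
#' singular vectors kept as the projection basis. A fixed sign convention
#' (largest-magnitude entry of each basis column nonnegative) makes the fit
#' reproducible across linear-algebra backends.
#'
#' @param x Training matrix, n samples x fused dim (n >= k, dim >= k).
#' @param n_components Number of retained components (default 5).
#' @param center Subtract column means before the SVD (default `TRUE`).
#' @return An `svd_projector`: `mean` (fused dim), `basis` (fused dim x k,
#'   orthonormal columns), `singular_values` (k, nonincreasing).
#' @export
fit_svd_projector <- function(x, n_components = 5L, center = TRUE) {
  x <- as.matrix(x)
  k <- as.integer(n_components)
  if (any(!is.finite(x))) abort_validation("training matrix has non-finite entries")
  if (nrow(x) < k || ncol(x) < k) {
    abort_validation(sprintf(
      "need at least %d rows and %d columns to fit %d components; got %d x %d",
      k, k, k, nrow(x), ncol(x)))
  }
  mu <- if (center) colMeans(x) else rep(0, ncol(x))
  xc <- sweep(x, 2L, mu, "-")
  sv <- svd(xc, nu = 0, nv = k)
  basis <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-|entry| of each column nonnegative
  for (j in seq_len(k)) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  structure(
    list(mean = mu, basis = basis,
         singular_values = sv$d[seq_len(k)],
         n_components = k, centered = center, input_dim = ncol(x)),
    class = "svd_projector"
  )
}

#' @export
print.svd_projector <- function(x, ...) {
  cat(sprintf("<svd_projector> %d -> %d features (centered: %s)\n",
              x$input_dim, x$n_components, x$centered))
  cat("singular values:", signif(x$singular_values, 4), "\n")
  invisible(x)
}

#' Project fused features onto the quantum-feature basis
#'
#' @param projector An `svd_projector`.
#' @param fused Numeric vector (fused dim), matrix (n x fused dim) or fused
#'   tibble from [merge_dataset()].
#' @return For a vector input, a numeric vector of length `n_components`; for
#'   matrix/tibble input a tibble (`subject_id` if available, `label` if
#'   available, `q1 ... qk`).
#' @export
svd_transform <- function(projector, fused) {
  stopifnot(inherits(projector, "svd_projector"))
  if (is.data.frame(fused)) {
    m <- feature_matrix(fused)
    meta <- fused[, intersect(c("subject_id", "label"), names(fused))]
  } else if (is.matrix(fused)) {
    m <- fused
    meta <- NULL
  } else {
    if (length(fused) != projector$input_dim) {
      abort_validation(sprintf("fused dim %d does not match projector dim %d",
                               length(fused), projector$input_dim))
    }
    return(as.numeric(crossprod(projector$basis,
                                as.numeric(fused) - projector$mean)))
  }
  if (ncol(m) != projector$input_dim) {
    abort_validation(sprintf("fused dim %d does not match projector dim %d",
                             ncol(m), projector$input_dim))
  }
  q <- sweep(m, 2L, projector$mean, "-") %*% projector$basis
  colnames(q) <- paste0("q", seq_len(ncol(q)))
  if (is.null(meta)) as_tibble(q) else bind_cols(meta, as_tibble(q))
}

#' Reconstruct fused features from their projection
#'
#' @param projector An `svd_projector`.
#' @param q Numeric vector (k) or matrix (n x k) of quantum features.
#' @return Reconstruction `basis %*% q + mean` (vector or matrix).
#' @export
svd_reconstruct <- function(projector, q) {
  stopifnot(inherits(projector, "svd_projector"))
  if (is.matrix(q)) {
    sweep(q %*% t(projector$basis), 2L, projector$mean, "+")
  } else {
    as.numeric(projector$basis %*% as.numeric(q)) + projector$mean
  }
}

#' Save / load an SVD projector as JSON
#'
#' The header records dimensions, centering flag and sign convention; arrays
#' are stored at full double precision.
#'
#' @param projector An `svd_projector`.
#' @param path JSON file path.
#' @return `save_svd_projector` returns `path` invisibly; `load_svd_projector`
#'   returns the projector.
#' @export
save_svd_projector <- function(projector, path) {
  jsonlite::write_json(list(
    type = "svd_projector", input_dim = projector$input_dim,
    n_components = projector$n_components, centered = projector$centered,
    sign_convention = "largest_abs_nonneg",
    mean = projector$mean, singular_values = projector$singular_values,
    basis = as.numeric(projector$basis)  # column-major flat
  ), path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_svd_projector
#' @export
load_svd_projector <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- matrix(as.numeric(j$basis), ncol = j$n_components)
  structure(
    list(mean = as.numeric(j$mean), basis = basis,
         singular_values = as.numeric(j$singular_values),
         n_components = as.integer(j$n_components),
         centered = isTRUE(j$centered), input_dim = as.integer(j$input_dim)),
    class = "svd_projector"
  )
}
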