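#' Fully connected classification head
#'
#' Maps the circuit's measured expectations to class probabilities through
#' fully connected layers of 100, 50, 20 and 3 neurons: ReLU hidden
#' activations, softmax output, He-style seeded initialization.
#'
#' @param layer_sizes Layer widths, default `c(100, 50, 20, 3)`; the last
#'   entry is the class count.
#' @param input_dim Input width (default 5, the measured qubits).
#' @param seed Initialization seed.
#' @return A `dense_head` with weight matrices `W` and biases `b` per layer.
#' @export
dense_head <- function(layer_sizes = c(100L, 50L, 20L, 3L), input_dim = 5L,
                       seed = 1L) {
  sizes <- as.integer(c(input_dim, layer_sizes))
  W <- vector("list", length(layer_sizes))
  b <- vector("list", length(layer_sizes))
  with_seed(seed, {
    for (i in seq_along(layer_sizes)) {
      W[[i]] <- matrix(rnorm(sizes[i] * sizes[i + 1], sd = sqrt(2 / sizes[i])),
                       nrow = sizes[i], ncol = sizes[i + 1])
      b[[i]] <- rep(0, sizes[i + 1])
    }
  })
  structure(list(W = W, b = b, layer_sizes = as.integer(layer_sizes),
                 input_dim = as.integer(input_dim)),
            class = "dense_head")
}

#' @export
print.dense_head <- function(x, ...) {
  cat(sprintf("<dense_head> %d -> %s\n", x$input_dim,
              paste(x$layer_sizes, collapse = " -> ")))
  invisible(x)
}

# Forward with cached pre/post activations for backprop. x: B x input_dim.
head_forward_cache <- function(head, x) {
  acts <- list(x)
  L <- length(head$W)
  for (i in seq_len(L)) {
    z <- sweep(acts[[i]] %*% head$W[[i]], 2L, head$b[[i]], "+")
    acts[[i + 1]] <- if (i < L) pmax(z, 0) else softmax(z)
  }
  acts
}

#' Head forward pass
#'
#' @param head A `dense_head`.
#' @param z Input vector (length `input_dim`) or matrix (samples x
#'   `input_dim`).
#' @return Class probabilities: vector of length `n_classes`, or a samples x
#'   `n_classes` matrix; rows sum to 1.
#' @export
head_forward <- function(head, z) {
  stopifnot(inherits(head, "dense_head"))
  vec <- !is.matrix(z)
  m <- if (vec) matrix(as.numeric(z), nrow = 1L) else z
  if (ncol(m) != head$input_dim) {
    abort_validation(sprintf("head expects %d inputs, got %d",
                             head$input_dim, ncol(m)))
  }
  p <- head_forward_cache(head, m)[[length(head$W) + 1L]]
  if (vec) as.numeric(p) else p
}

#' Head loss and gradients
#'
#' Softmax cross-entropy loss with full backpropagation; the gradient with
#' respect to the head's input is returned so the quantum layer can be
#' chained in front.
#'
#' @param head A `dense_head`.
#' @param z Input vector or batch matrix.
#' @param label Integer class labels in `1..n_classes` (one per sample).
#' @return List: `loss` (mean cross-entropy, >= 0), `grads`
#'   (`W`/`b` lists matching the head layout), `input_grad` (same shape as
#'   `z`), `probs`.
#' @export
head_loss_and_grads <- function(head, z, label) {
  stopifnot(inherits(head, "dense_head"))
  vec <- !is.matrix(z)
  m <- if (vec) matrix(as.numeric(z), nrow = 1L) else z
  nc <- head$layer_sizes[length(head$layer_sizes)]
  label <- as.integer(label)
  if (any(is.na(label)) || any(label < 1L) || any(label > nc)) {
    abort_validation(sprintf("labels must be integers in 1..%d", nc))
  }
  if (length(label) != nrow(m)) abort_validation("one label per sample required")
  B <- nrow(m)
  acts <- head_forward_cache(head, m)
  L <- length(head$W)
  p <- acts[[L + 1L]]
  loss <- -mean(log(pmax(p[cbind(seq_len(B), label)], 1e-300)))
  delta <- p
  delta[cbind(seq_len(B), label)] <- delta[cbind(seq_len(B), label)] - 1
  delta <- delta / B
  gW <- vector("list", L); gb <- vector("list", L)
  for (i in L:1) {
    gW[[i]] <- t(acts[[i]]) %*% delta
    gb[[i]] <- colSums(delta)
    if (i > 1L) {
      delta <- (delta %*% t(head$W[[i]])) * (acts[[i]] > 0)
    } else {
      delta <- delta %*% t(head$W[[1]])
    }
  }
  input_grad <- if (vec) as.numeric(delta) else delta
  list(loss = loss,
       grads = list(W = gW, b = gb),
       input_grad = input_grad,
       probs = if (vec) as.numeric(p) else p)
}
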