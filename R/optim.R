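# Minimal Adam optimizer over a named list of numeric parameters
# (vectors/matrices). Defaults beta1 = 0.9, beta2 = 0.999, eps = 1e-8.

adam_init <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zeros <- map(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(state, params, grads, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, params = params)
}
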