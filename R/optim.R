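# Adaptive-moment stochastic gradient optimizer (with optional max-variant
# second moment), operating on a named list of numeric vectors/arrays.

adam_init <- function(par) {
  list(m = lapply(par, function(p) 0 * p),
       v = lapply(par, function(p) 0 * p),
       vhat = lapply(par, function(p) 0 * p),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, amsgrad = FALSE) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    vv <- if (amsgrad) {
      state$vhat[[nm]] <- pmax(state$vhat[[nm]], state$v[[nm]])
      state$vhat[[nm]]
    } else state$v[[nm]]
    par[[nm]] <- par[[nm]] - lr * (state$m[[nm]] / bc1) / (sqrt(vv / bc2) + eps)
  }
  list(par = par, state = state)
}
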