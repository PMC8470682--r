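# Adaptive-moment (Adam) optimizer over the nested parameter lists of a
# polyp_net: params is a list (one element per layer) of named numeric
# arrays; gradients mirror that structure.

adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(a)
    if (is.null(dim(a))) numeric(length(a)) else array(0, dim(a)))
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g * g
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * (state$m[[i]][[nm]] / bc1) /
        (sqrt(state$v[[i]][[nm]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

grads_add <- function(a, b) {
  for (i in seq_along(a))
    for (nm in names(a[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  a
}

grads_scale <- function(a, s) {
  for (i in seq_along(a))
    for (nm in names(a[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] * s
  a
}

`%||%` <- function(x, y) if (is.null(x)) y else x
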