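# Minimal dense-network machinery used by the DMVAE: tanh MLPs with
# reverse-mode gradients, nested-parameter utilities, and an Adam-family
# optimizer. Internal only; the model surface lives in dmvae.R.

mlp_init <- function(sizes, seed = NULL) {
  stopifnot(length(sizes) >= 2)
  build <- function() {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1)) {
      fan_in <- sizes[l]
      W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1], sd = 1 / sqrt(fan_in)),
                       fan_in, sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
    list(W = W, b = b) # sizes are kept in the model's architecture spec
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

# Forward pass; tanh on hidden layers, linear output. Returns the output
# and the per-layer post-activation cache needed for backprop.
mlp_forward <- function(net, X) {
  acts <- vector("list", length(net$W) + 1)
  acts[[1]] <- X
  H <- X
  L <- length(net$W)
  for (l in seq_len(L)) {
    Z <- H %*% net$W[[l]]
    Z <- sweep(Z, 2, net$b[[l]], "+")
    H <- if (l < L) tanh(Z) else Z
    acts[[l + 1]] <- H
  }
  list(out = H, acts = acts)
}

# Reverse pass from dL/d(out); returns parameter gradients and dL/d(input).
mlp_backward <- function(net, acts, d_out) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  dH <- d_out
  for (l in rev(seq_len(L))) {
    dZ <- if (l < L) dH * (1 - acts[[l + 1]]^2) else dH
    gW[[l]] <- crossprod(acts[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    dH <- tcrossprod(dZ, net$W[[l]])
  }
  list(W = gW, b = gb, d_in = dH)
}

# ---- nested numeric-list utilities (parameters and their gradients) ----

nl_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) {
      if (is.numeric(a[[i]]) || is.list(a[[i]])) {
        out[[i]] <- nl_map(f, a[[i]], if (is.null(b)) NULL else b[[i]])
      }
    }
    out
  } else if (is.numeric(a)) {
    if (is.null(b)) f(a) else f(a, b)
  } else {
    a
  }
}

nl_zeros_like <- function(a) nl_map(function(x) x * 0, a)

nl_flatten <- function(a) {
  if (is.list(a)) {
    unlist(lapply(a, function(el) {
      if (is.numeric(el) || is.list(el)) nl_flatten(el) else numeric(0)
    }), use.names = FALSE)
  } else if (is.numeric(a)) {
    as.numeric(a)
  } else {
    numeric(0)
  }
}

nl_unflatten <- function(template, values) {
  pos <- 0L
  fill <- function(a) {
    if (is.list(a)) {
      for (i in seq_along(a)) {
        if (is.numeric(a[[i]]) || is.list(a[[i]])) a[[i]] <- fill(a[[i]])
      }
      a
    } else if (is.numeric(a)) {
      n <- length(a)
      out <- a
      out[] <- values[(pos + 1L):(pos + n)]
      pos <<- pos + n
      out
    } else {
      a
    }
  }
  out <- fill(template)
  stopifnot(pos == length(values))
  out
}

# ---- Adam-family optimizer over nested parameter lists ----

adam_init <- function(params) {
  list(m = nl_zeros_like(params), v = nl_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nl_map(function(m, g) beta1 * m + (1 - beta1) * g,
                    state$m, grads)
  state$v <- nl_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                    state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- nl_map(function(m) m / bc1, state$m)
  vhat <- nl_map(function(v) v / bc2, state$v)
  step <- nl_map(function(m, v) lr * m / (sqrt(v) + eps), mhat, vhat)
  params <- nl_map(function(p, s) p - s, params, step)
  list(params = params, state = state)
}
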