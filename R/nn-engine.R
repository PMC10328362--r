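# Feedforward engine used by both the MTL LINA attention subnetwork and the
# single-task baseline: hidden blocks of affine -> batch-norm -> leaky-ReLU
# -> dropout, plus a linear output layer. Forward, reverse-mode gradients
# and the Adam update are implemented here in base R; gradients are
# verified against central finite differences in the test suite.
#
# Conventions: data are row-major batches (n x features). Batch-norm
# normalizes with biased batch variance in training mode and with
# accumulated running statistics (momentum 0.1) in eval mode. Dropout is
# "inverted" (activations scaled by 1/(1-rate) at train time) so eval mode
# needs no rescaling.

BN_EPS <- 1e-5

# broadcast a length-k vector across the rows of an n x k matrix;
# the BLAS outer product is markedly faster here than rep()/matrix(byrow=)
rowrep <- function(v, n) tcrossprod(rep.int(1, n), v)

sigmoid <- function(z) 1 / (1 + exp(-z))

leaky_relu <- function(v, slope) pmax(v, 0) + slope * pmin(v, 0)

# Kaiming-uniform initialization for a fan_in x fan_out weight matrix
init_weight <- function(fan_in, fan_out) {
  bound <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * fan_out, -bound, bound), fan_in, fan_out)
}

mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden)
  layers <- vector("list", length(hidden))
  for (l in seq_along(hidden)) {
    k <- sizes[l + 1]
    layers[[l]] <- list(W = init_weight(sizes[l], k),
                        b = numeric(k),
                        gamma = rep(1, k),
                        beta = numeric(k),
                        run_mean = numeric(k),
                        run_var = rep(1, k))
  }
  list(hidden = layers,
       out = list(W = init_weight(sizes[length(sizes)], n_out),
                  b = numeric(n_out)))
}

# forward through one hidden block; returns output, cache for backprop and
# (in training mode) the layer with updated running statistics
block_forward <- function(layer, H, training, dropout, slope) {
  n <- nrow(H)
  U <- H %*% layer$W + rowrep(layer$b, n)
  if (training) {
    mu <- colMeans(U)
    centered <- U - rowrep(mu, n)
    v <- colMeans(centered^2)                    # biased batch variance
    layer$run_mean <- 0.9 * layer$run_mean + 0.1 * mu
    layer$run_var <- 0.9 * layer$run_var + 0.1 * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
    centered <- U - rowrep(mu, n)
  }
  std <- sqrt(v + BN_EPS)
  Uhat <- centered / rowrep(std, n)
  V <- Uhat * rowrep(layer$gamma, n) + rowrep(layer$beta, n)
  act <- leaky_relu(V, slope)
  mask <- NULL
  if (training && dropout > 0) {
    mask <- stats::runif(length(act)) >= dropout
    act <- act * mask / (1 - dropout)
  }
  list(out = act, layer = layer,
       cache = list(H = H, centered = centered, std = std, Uhat = Uhat,
                    V = V, mask = mask, training = training))
}

# gradients of one hidden block given d(loss)/d(block output)
block_backward <- function(layer, cache, dOut, dropout, slope) {
  n <- nrow(dOut)
  dAct <- if (!is.null(cache$mask)) dOut * cache$mask / (1 - dropout) else dOut
  dV <- dAct * (slope + (1 - slope) * (cache$V > 0))
  dgamma <- colSums(dV * cache$Uhat)
  dbeta <- colSums(dV)
  dUhat <- dV * rowrep(layer$gamma, n)
  if (cache$training) {
    # batch statistics depend on U: full batch-norm backward
    inv <- rowrep(1 / cache$std, n)
    dvar <- colSums(dUhat * cache$centered) * (-0.5) / cache$std^3
    dmu <- -colSums(dUhat) / cache$std
    dU <- dUhat * inv +
      cache$centered * rowrep(2 * dvar / n, n) +
      rowrep(dmu / n, n)
  } else {
    dU <- dUhat * rowrep(1 / cache$std, n)
  }
  # zero entries for the running statistics keep the gradient tree
  # congruent with the parameter tree (Adam then leaves them untouched)
  list(grads = list(W = crossprod(cache$H, dU),
                    b = colSums(dU),
                    gamma = dgamma,
                    beta = dbeta,
                    run_mean = 0 * layer$run_mean,
                    run_var = 0 * layer$run_var),
       dH = dU %*% t(layer$W))
}

mlp_forward <- function(net, X, training = FALSE, dropout = 0, slope = 0.01) {
  caches <- vector("list", length(net$hidden))
  H <- X
  for (l in seq_along(net$hidden)) {
    fw <- block_forward(net$hidden[[l]], H, training, dropout, slope)
    H <- fw$out
    net$hidden[[l]] <- fw$layer
    caches[[l]] <- fw$cache
  }
  out <- H %*% net$out$W + rowrep(net$out$b, nrow(H))
  list(out = out, net = net, caches = caches, top = H)
}

# backprop d(loss)/d(mlp output) through the whole net; dX not needed by
# any caller (inputs are genotypes) and is not computed
mlp_backward <- function(net, fw, dOut, dropout = 0, slope = 0.01) {
  grads <- list(hidden = vector("list", length(net$hidden)),
                out = list(W = crossprod(fw$top, dOut),
                           b = colSums(dOut)))
  dH <- dOut %*% t(net$out$W)
  for (l in rev(seq_along(net$hidden))) {
    bk <- block_backward(net$hidden[[l]], fw$caches[[l]], dH, dropout, slope)
    grads$hidden[[l]] <- bk$grads
    dH <- bk$dH
  }
  grads
}

# eval-mode input-output Jacobian of the mlp at a single input row x
# (exact away from leaky-ReLU kinks: the eval-mode map is piecewise affine)
mlp_jacobian <- function(net, x, slope = 0.01) {
  fw <- mlp_forward(net, matrix(x, 1), training = FALSE, slope = slope)
  J <- diag(length(x))
  for (l in seq_along(net$hidden)) {
    layer <- net$hidden[[l]]
    cache <- fw$caches[[l]]
    scale <- layer$gamma / cache$std                 # batch-norm slope
    act_slope <- slope + (1 - slope) * (cache$V[1, ] > 0)
    J <- J %*% layer$W * rowrep(scale * act_slope, nrow(J))
  }
  J %*% net$out$W                                    # d(out_j)/d(x_k) at [k, j]
}

# ---- parameter-tree utilities (params, grads and Adam moments share the
# same nested-list shape; leaves are numeric vectors/matrices) ----

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v) {
    lr * (m / c1) / (sqrt(v / c2) + eps)
  })
  list(params = tree_map2(params, upd, `-`), state = state)
}
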