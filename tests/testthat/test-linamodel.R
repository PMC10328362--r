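test_that("initialization is seed-deterministic with the documented shapes", {
  cfg <- lina_config(10, 3, hidden = c(8, 6, 4))
  p1 <- lina_init(cfg, seed = 5)
  p2 <- lina_init(cfg, seed = 5)
  p3 <- lina_init(cfg, seed = 6)
  expect_identical(p1, p2)
  expect_identical(dim(p1$K), c(3L, 10L))
  expect_length(p1$B, 3)
  expect_identical(dim(p1$attention$hidden[[1]]$W), c(10L, 8L))
  expect_identical(dim(p1$attention$out$W), c(4L, 10L))
  X <- matrix(sample(0:2, 50, TRUE), 5, 10)
  expect_false(identical(lina_forward(p1, X, cfg), lina_forward(p3, X, cfg)))
})

test_that("a constant attention subnetwork returns its constant for any input, deterministically", {
  cfg <- lina_config(4, 2, hidden = c(3, 3, 2), dropout_rate = 0.5)
  a0 <- c(0.5, -1, 2, 0)
  p <- constant_attention_params(cfg, a0, K = matrix(0, 2, 4), B = c(0, 0))
  X <- matrix(sample(0:2, 40, TRUE), 10, 4)
  A1 <- lina_attention(p, X, cfg, training = FALSE)
  A2 <- lina_attention(p, X, cfg, training = FALSE)
  expect_equal(A1, matrix(a0, 10, 4, byrow = TRUE), ignore_attr = TRUE)
  expect_identical(A1, A2)  # eval mode is exactly idempotent
})

test_that("a tiny attention net with known weights matches hand matrix arithmetic", {
  # m = 2, hidden 2/2/2; batch-norm running stats chosen so the eval-mode
  # normalization is the identity (run_mean 0, run_var 1 - eps, gamma 1)
  cfg <- lina_config(2, 1, hidden = c(2, 2, 2), leaky_slope = 0.1)
  p <- lina_init(cfg, seed = 1)
  W1 <- matrix(c(1, -1, 2, 0.5), 2, 2)
  W2 <- matrix(c(0.5, 0, -1, 1), 2, 2)
  W3 <- matrix(c(1, 2, -0.5, 1), 2, 2)
  Wo <- matrix(c(1, 0, 0, -1), 2, 2)
  for (l in 1:3) {
    p$attention$hidden[[l]]$W <- list(W1, W2, W3)[[l]]
    p$attention$hidden[[l]]$b <- c(0.1, -0.2)
    p$attention$hidden[[l]]$gamma <- c(1, 1)
    p$attention$hidden[[l]]$beta <- c(0, 0)
    p$attention$hidden[[l]]$run_mean <- c(0, 0)
    p$attention$hidden[[l]]$run_var <- c(1, 1) - 1e-5
  }
  p$attention$out$W <- Wo
  p$attention$out$b <- c(0.3, 0)
  x <- c(2, 1)
  leaky <- function(v) ifelse(v > 0, v, 0.1 * v)
  h1 <- leaky(as.vector(x %*% W1) + c(0.1, -0.2))
  h2 <- leaky(as.vector(h1 %*% W2) + c(0.1, -0.2))
  h3 <- leaky(as.vector(h2 %*% W3) + c(0.1, -0.2))
  a_hand <- as.vector(h3 %*% Wo) + c(0.3, 0)
  A <- lina_attention(p, matrix(x, 1), cfg, training = FALSE)
  expect_equal(as.vector(A), a_hand, tolerance = 1e-12)
})

test_that("the forward pass is exactly sigmoid(K (A o X) + B)", {
  # scalar closed form: d=1, m=2, A=(1,1), K=(1,-1), B=0, x=(2,0) -> sigma(2)
  cfg <- lina_config(2, 1, hidden = c(2, 2, 2))
  p <- constant_attention_params(cfg, c(1, 1), K = matrix(c(1, -1), 1, 2),
                                 B = 0)
  expect_equal(as.vector(lina_forward(p, c(2, 0), cfg)),
               1 / (1 + exp(-2)), tolerance = 1e-12)

  # all-zero input annihilates the skip product: Y = sigmoid(B) for any F
  cfg2 <- lina_config(5, 3, hidden = c(4, 3, 2))
  p2 <- lina_init(cfg2, seed = 2)
  p2$B <- c(-1, 0, 2)
  expect_equal(as.vector(lina_forward(p2, rep(0, 5), cfg2)),
               plogis(c(-1, 0, 2)), tolerance = 1e-12)

  # with constant attention the model reduces to a per-trait logistic model
  # with coefficients K_tj * a_j
  a0 <- c(0.5, 2, -1)
  K <- matrix(rnorm(6), 2, 3)
  B <- c(0.3, -0.7)
  cfg3 <- lina_config(3, 2, hidden = c(2, 2, 2))
  p3 <- constant_attention_params(cfg3, a0, K, B)
  X <- matrix(sample(0:2, 30, TRUE), 10, 3)
  glm_probs <- plogis(X %*% t(K * rep(a0, each = 2)) +
                        matrix(B, 10, 2, byrow = TRUE))
  expect_equal(lina_forward(p3, X, cfg3), glm_probs, tolerance = 1e-12)
})

test_that("the loss decomposes exactly into weighted cross-entropies plus the K-norm penalty", {
  # uninformative model: p = 0.5 everywhere -> E = ln 2
  cfg <- lina_config(2, 1, hidden = c(2, 2, 2), penalty = 0)
  p <- constant_attention_params(cfg, c(1, 1), K = matrix(0, 1, 2), B = 0)
  X <- matrix(sample(0:2, 20, TRUE), 10, 2)
  y <- matrix(rbinom(10, 1, 0.5), 10, 1)
  l <- mtl_loss(p, X, y, cfg)
  expect_equal(l$per_trait, log(2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(l$total, log(2), tolerance = 1e-12)

  # penalty by hand: 2x2 K of 2s, beta 1e-3 -> 1e-3 * sqrt(16) = 4e-3
  cfg2 <- lina_config(2, 2, hidden = c(2, 2, 2), penalty = 1e-3)
  p2 <- constant_attention_params(cfg2, c(1, 1),
                                  K = matrix(2, 2, 2), B = c(0, 0))
  l2 <- mtl_loss(p2, X, cbind(y, y), cfg2)
  expect_equal(l2$penalty, 4e-3, tolerance = 1e-15)
  expect_equal(l2$total, sum(cfg2$loss_weights * l2$per_trait) + l2$penalty,
               tolerance = 1e-12)

  # perfect-prediction limit drives the loss to ~0 when beta = 0
  p3 <- constant_attention_params(cfg, c(1, 1), K = matrix(0, 1, 2),
                                  B = 30)
  l3 <- mtl_loss(p3, X, matrix(1, 10, 1), cfg)
  expect_lt(l3$total, 1e-10)

  expect_error(mtl_loss(p, X, matrix(0.5, 10, 1), cfg), "binary")
})

test_that("training-mode gradients match central finite differences (full backprop oracle)", {
  set.seed(42)
  m <- 5; d <- 2; n <- 8
  cfg <- lina_config(m, d, hidden = c(4, 3, 2), dropout_rate = 0,
                     penalty = 1e-3)
  p0 <- lina_init(cfg, seed = 3)
  X <- matrix(as.double(sample(0:2, n * m, TRUE)), n, m)
  Y <- matrix(rbinom(n * d, 1, 0.4), n, d)
  gr <- linaprs:::lina_grad(p0, X, Y, cfg)
  loss_at <- function(p) {
    fw <- linaprs:::lina_forward_full(p, X, cfg, training = TRUE)
    E <- colMeans(linaprs:::bce(fw$prob, Y))
    sum(cfg$loss_weights * E) + linaprs:::penalty_value(p$K, cfg)
  }
  set_in <- function(p, path, val) {
    if (length(path) == 1) p[[path[[1]]]] <- val
    else p[[path[[1]]]] <- set_in(p[[path[[1]]]], path[-1], val)
    p
  }
  get_in <- function(p, path) { for (k in path) p <- p[[k]]; p }
  paths <- list(list("K"), list("B"),
                list("attention", "out", "W"), list("attention", "out", "b"))
  for (l in 1:3) for (f in c("W", "gamma", "beta")) {
    paths <- c(paths, list(list("attention", "hidden", l, f)))
  }
  h <- 1e-6
  for (path in paths) {
    g <- get_in(gr$grads, path)
    v0 <- get_in(p0, path)
    fd <- vapply(seq_along(v0), function(i) {
      vp <- v0; vp[i] <- vp[i] + h
      vm <- v0; vm[i] <- vm[i] - h
      (loss_at(set_in(p0, path, vp)) - loss_at(set_in(p0, path, vm))) / (2 * h)
    }, 0)
    expect_lt(max(abs(fd - as.vector(g)) / (1e-3 + abs(fd))), 1e-4,
              label = paste("grad check", paste(unlist(path), collapse = "$")))
  }
})

test_that("single-task gradients also match finite differences and outputs stay in (0,1)", {
  set.seed(7)
  cfg <- stl_config(4, hidden = c(3, 3, 2), dropout_rate = 0)
  p0 <- stl_init(cfg, seed = 2)
  X <- matrix(as.double(sample(0:2, 24, TRUE)), 6, 4)
  y <- matrix(rbinom(6, 1, 0.5))
  gr <- linaprs:::stl_grad(p0, X, y, cfg)
  loss_at <- function(p) {
    fw <- linaprs:::mlp_forward(p$net, X, training = TRUE,
                                dropout = 0, slope = cfg$leaky_slope)
    mean(linaprs:::bce(linaprs:::sigmoid(fw$out), y))
  }
  h <- 1e-6
  v0 <- p0$net$hidden[[1]]$W
  fd <- vapply(seq_along(v0), function(i) {
    pp <- p0; pp$net$hidden[[1]]$W[i] <- v0[i] + h
    pm <- p0; pm$net$hidden[[1]]$W[i] <- v0[i] - h
    (loss_at(pp) - loss_at(pm)) / (2 * h)
  }, 0)
  expect_lt(max(abs(fd - as.vector(gr$grads$net$hidden[[1]]$W)) /
                  (1e-3 + abs(fd))), 1e-4)
  prob <- stl_forward(p0, X, cfg)
  expect_true(all(prob > 0 & prob < 1))
  expect_identical(prob, stl_forward(p0, X, cfg))  # eval determinism
})

test_that("the linearization identity holds for random models in eval mode", {
  set.seed(11)
  for (i in 1:10) {
    m <- sample(3:8, 1); d <- sample(1:3, 1)
    cfg <- lina_config(m, d, hidden = c(5, 4, 3))
    p <- lina_init(cfg, seed = i)
    X <- matrix(as.double(sample(0:2, 6 * m, TRUE)), 6, m)
    probs <- lina_forward(p, X, cfg, training = FALSE)
    A <- lina_attention(p, X, cfg, training = FALSE)
    # reference route: plain matrix arithmetic from extracted (K, A, B)
    ref <- 1 / (1 + exp(-((A * X) %*% t(p$K) +
                            matrix(p$B, 6, d, byrow = TRUE))))
    expect_lt(max(abs(probs - ref) / pmax(abs(ref), 1e-12)), 1e-5)
  }
})

test_that("eval-mode attention is locally linear (finite-difference Jacobians agree across step sizes)", {
  set.seed(13)
  cfg <- lina_config(4, 1, hidden = c(4, 3, 2))
  p <- lina_init(cfg, seed = 4)
  x <- runif(4, 0.2, 1.8)   # interior point, away from kinks w.h.p.
  f <- function(v) as.vector(lina_attention(p, matrix(v, 1), cfg))
  for (j in 1:4) {
    fj <- function(v) f(v)[j]
    g3 <- fd_grad(fj, x, h = 1e-3)
    g4 <- fd_grad(fj, x, h = 1e-4)
    expect_equal(g3, g4, tolerance = 1e-5)
  }
})

test_that("checkpoints round-trip through the JSON container", {
  cfg <- lina_config(6, 2, hidden = c(4, 3, 2))
  p <- lina_init(cfg, seed = 9)
  tmp <- tempfile(fileext = ".json")
  write_checkpoint(p, cfg, tmp, kind = "mtl")
  back <- read_checkpoint(tmp)
  X <- matrix(as.double(sample(0:2, 30, TRUE)), 5, 6)
  expect_equal(lina_forward(back$params, X, back$config),
               lina_forward(p, X, cfg), tolerance = 1e-12)
  notck <- tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), notck)
  expect_error(read_checkpoint(notck), "not a linaprs checkpoint")
})
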