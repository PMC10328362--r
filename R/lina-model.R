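#' MTL LINA model configuration
#'
#' The multi-task linearizing architecture predicts d binary traits from an
#' m-SNP genotype vector X as
#' \deqn{Y = S(K (A \circ X) + B), \qquad A = F(X),}
#' where S is the element-wise sigmoid, K a d x m coefficient matrix, B a
#' d-vector of biases, and A an m-unit attention vector produced by a
#' feedforward subnetwork F with three hidden layers (leaky-ReLU, dropout,
#' batch normalization) and a linear attention layer. Given A the model is
#' exactly linear in X, which is what makes its interpretation model-wise
#' exact. The training loss is \eqn{W^T E + \beta \|K\|_2} with E the
#' per-trait mean cross-entropies, W nonnegative trait weights and
#' \eqn{\|K\|_2} the (Frobenius) L2 norm of K.
#'
#' @param n_snps m, input SNPs.
#' @param n_traits d, output traits.
#' @param hidden sizes of the three hidden layers of F (default
#'   \code{c(1000, 250, 50)}).
#' @param dropout_rate dropout rate in the hidden layers (default 0.5).
#' @param leaky_slope negative slope of the leaky-ReLU (default 0.01).
#' @param penalty regularization weight \eqn{\beta} on \eqn{\|K\|_2}
#'   (default 1e-3).
#' @param loss_weights trait weights W (default all 1).
#' @param squared_penalty penalize \eqn{\|K\|_2^2} instead of
#'   \eqn{\|K\|_2}; off by default (the norm itself is the contract).
#' @return object of class \code{"lina_config"}.
#' @export
lina_config <- function(n_snps, n_traits, hidden = c(1000, 250, 50),
                        dropout_rate = 0.5, leaky_slope = 0.01,
                        penalty = 1e-3, loss_weights = NULL,
                        squared_penalty = FALSE) {
  if (length(hidden) != 3) stop("hidden must give three layer sizes")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (penalty < 0) stop("penalty must be >= 0")
  if (is.null(loss_weights)) loss_weights <- rep(1, n_traits)
  if (length(loss_weights) != n_traits || any(loss_weights < 0)) {
    stop("loss_weights must be ", n_traits, " nonnegative values")
  }
  structure(list(n_snps = as.integer(n_snps),
                 n_traits = as.integer(n_traits),
                 hidden = as.integer(hidden),
                 dropout_rate = dropout_rate,
                 leaky_slope = leaky_slope,
                 penalty = penalty,
                 loss_weights = loss_weights,
                 squared_penalty = squared_penalty),
            class = "lina_config")
}

#' Initialize MTL LINA parameters
#'
#' Kaiming-uniform weights for the attention subnetwork and K; zero biases.
#' The attention subnetwork maps m -> hidden[1] -> hidden[2] -> hidden[3]
#' -> m with a linear output (attention) layer.
#'
#' @param config a [lina_config()].
#' @param seed integer seed; identical seeds give identical parameters.
#' @return parameter list with elements \code{attention} (subnetwork
#'   weights and batch-norm statistics), \code{K} (d x m) and \code{B} (d).
#' @export
lina_init <- function(config, seed = 1L) {
  set.seed(seed %% .Machine$integer.max)
  m <- config$n_snps
  list(attention = mlp_init(m, config$hidden, m),
       K = init_weight(m, config$n_traits) |> t(),
       B = numeric(config$n_traits))
}

#' Attention vectors A = F(X)
#'
#' @param params parameters from [lina_init()] (or a fitted model's
#'   \code{$params}).
#' @param X n x m genotype batch.
#' @param config the model's [lina_config()].
#' @param training logical; training mode uses batch statistics and
#'   dropout, eval mode (default) is deterministic and piecewise linear
#'   in X.
#' @return n x m matrix of attention vectors.
#' @export
lina_attention <- function(params, X, config, training = FALSE) {
  X <- as_input_matrix(X, config$n_snps)
  mlp_forward(params$attention, X, training = training,
              dropout = config$dropout_rate,
              slope = config$leaky_slope)$out
}

#' Forward pass of MTL LINA
#'
#' Computes exactly \code{sigmoid(K (A o X) + B)} with \code{A = F(X)}:
#' the element-wise skip multiplication of attention and input is the
#' architecture's defining contract.
#'
#' @inheritParams lina_attention
#' @return n x d matrix of per-trait probabilities in (0, 1).
#' @export
lina_forward <- function(params, X, config, training = FALSE) {
  X <- as_input_matrix(X, config$n_snps)
  fw <- lina_forward_full(params, X, config, training = training)
  fw$prob
}

# full forward with caches (internal, used by the gradient step)
lina_forward_full <- function(params, X, config, training = FALSE) {
  afw <- mlp_forward(params$attention, X, training = training,
                     dropout = config$dropout_rate,
                     slope = config$leaky_slope)
  A <- afw$out
  M <- A * X
  Z <- M %*% t(params$K) + rowrep(params$B, nrow(X))
  list(prob = sigmoid(Z), score = Z, A = A, M = M, afw = afw,
       params_bn = c(list(attention = afw$net),
                     params[setdiff(names(params), "attention")]))
}

as_input_matrix <- function(X, m) {
  if (inherits(X, "genotype_dataset")) X <- fetch_genotypes(X)
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != m) stop("input has ", ncol(X), " columns; model expects ", m)
  X
}

#' Multi-task training loss
#'
#' Per-trait mean binary cross-entropy E over the batch, combined as
#' \code{total = sum(W * E) + penalty_term} where the penalty term is
#' \eqn{\beta \|K\|_2} (Frobenius norm; or its square if the config says
#' so). The decomposition \code{total = W'E + penalty} holds exactly by
#' construction.
#'
#' @param params model parameters.
#' @param X n x m genotype batch.
#' @param Y_true n x d binary outcome matrix.
#' @param config a [lina_config()].
#' @param training forward mode for the loss evaluation.
#' @return object of class \code{"lina_loss"}: list with \code{per_trait}
#'   (E, length d), \code{penalty} and \code{total}.
#' @export
mtl_loss <- function(params, X, Y_true, config, training = FALSE) {
  X <- as_input_matrix(X, config$n_snps)
  Y_true <- as.matrix(Y_true)
  if (!all(Y_true %in% c(0, 1))) stop("Y_true must be binary 0/1")
  if (nrow(Y_true) != nrow(X) || ncol(Y_true) != config$n_traits) {
    stop("Y_true must be n x n_traits")
  }
  p <- lina_forward(params, X, config, training = training)
  E <- colMeans(bce(p, Y_true))
  pen <- penalty_value(params$K, config)
  structure(list(per_trait = E, penalty = pen,
                 total = sum(config$loss_weights * E) + pen),
            class = "lina_loss")
}

#' @export
print.lina_loss <- function(x, ...) {
  cat(sprintf("loss %.6f = sum(W*E) %.6f + penalty %.6f\n",
              x$total, x$total - x$penalty, x$penalty))
  invisible(x)
}

bce <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

penalty_value <- function(K, config) {
  fro <- sqrt(sum(K^2))
  if (config$squared_penalty) config$penalty * fro^2 else config$penalty * fro
}

# gradient of the penalty wrt K (subgradient 0 at K = 0)
penalty_grad <- function(K, config) {
  if (config$squared_penalty) return(2 * config$penalty * K)
  fro <- sqrt(sum(K^2))
  if (fro == 0) 0 * K else config$penalty * K / fro
}

# one training-mode forward/backward; returns loss, gradient tree (congruent
# with params) and the params with refreshed batch-norm running statistics
lina_grad <- function(params, X, Y, config) {
  n <- nrow(X)
  fw <- lina_forward_full(params, X, config, training = TRUE)
  E <- colMeans(bce(fw$prob, Y))
  # dL/dZ for mean cross-entropy, trait-weighted
  dZ <- (fw$prob - Y) * rowrep(config$loss_weights / n, n)
  gK <- t(crossprod(fw$M, dZ))                     # d x m
  gB <- colSums(dZ)
  dM <- dZ %*% params$K
  dA <- dM * X
  g_att <- mlp_backward(fw$afw$net, fw$afw, dA,
                        dropout = config$dropout_rate,
                        slope = config$leaky_slope)
  grads <- list(attention = g_att,
                K = gK + penalty_grad(params$K, config),
                B = gB)
  list(loss = sum(config$loss_weights * E) + penalty_value(params$K, config),
       grads = grads, params = fw$params_bn)
}

# ---- single-task baseline -------------------------------------------------

#' Single-task baseline configuration
#'
#' A plain feedforward net (three hidden layers with leaky-ReLU, dropout
#' and batch normalization, default sizes 1000/250/50) with one sigmoid
#' output, trained with binary cross-entropy. This is the per-trait
#' comparator for the multi-task model.
#'
#' @inheritParams lina_config
#' @return object of class \code{"stl_config"}.
#' @export
stl_config <- function(n_snps, hidden = c(1000, 250, 50),
                       dropout_rate = 0.5, leaky_slope = 0.01) {
  if (length(hidden) != 3) stop("hidden must give three layer sizes")
  structure(list(n_snps = as.integer(n_snps),
                 n_traits = 1L,
                 hidden = as.integer(hidden),
                 dropout_rate = dropout_rate,
                 leaky_slope = leaky_slope),
            class = "stl_config")
}

#' @rdname stl_config
#' @param config an \code{stl_config}.
#' @param seed integer seed.
#' @export
stl_init <- function(config, seed = 1L) {
  set.seed(seed %% .Machine$integer.max)
  list(net = mlp_init(config$n_snps, config$hidden, 1L))
}

#' Forward pass of the single-task baseline
#'
#' @param params parameters from [stl_init()].
#' @param X n x m genotype batch.
#' @param config an [stl_config()].
#' @param training forward mode.
#' @return length-n vector of probabilities in (0, 1).
#' @export
stl_forward <- function(params, X, config, training = FALSE) {
  X <- as_input_matrix(X, config$n_snps)
  fw <- mlp_forward(params$net, X, training = training,
                    dropout = config$dropout_rate,
                    slope = config$leaky_slope)
  as.vector(sigmoid(fw$out))
}

stl_grad <- function(params, X, y, config) {
  n <- nrow(X)
  fw <- mlp_forward(params$net, X, training = TRUE,
                    dropout = config$dropout_rate,
                    slope = config$leaky_slope)
  p <- sigmoid(fw$out)
  dZ <- (p - y) / n
  grads <- list(net = mlp_backward(fw$net, fw, dZ,
                                   dropout = config$dropout_rate,
                                   slope = config$leaky_slope))
  list(loss = mean(bce(p, y)), grads = grads,
       params = list(net = fw$net))
}

# ---- checkpoint container -------------------------------------------------

#' Write / read a model checkpoint
#'
#' Single-file JSON container (schema \code{linaprs-checkpoint v1}) holding
#' the model kind, its configuration, every weight and the batch-norm
#' running statistics, plus optional trait/SNP annotation, so a model can be
#' reloaded for prediction or interpretation without retraining.
#'
#' @param params parameter list (MTL or STL).
#' @param config the matching config object.
#' @param path file to write.
#' @param kind \code{"mtl"} or \code{"stl"}.
#' @param extra optional named list of annotation (trait names, SNP ids,
#'   epoch ...) stored verbatim.
#' @return \code{path} invisibly / for \code{read_checkpoint} a list with
#'   \code{params}, \code{config}, \code{kind}, \code{extra}.
#' @export
write_checkpoint <- function(params, config, path, kind = "mtl",
                             extra = list()) {
  obj <- list(schema = "linaprs-checkpoint", version = 1L, kind = kind,
              config = unclass(config), params = params, extra = extra)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (!identical(unlist(obj$schema), "linaprs-checkpoint")) {
    stop("not a linaprs checkpoint: ", path)
  }
  kind <- unlist(obj$kind)
  cfg <- lapply(obj$config, function(v) if (length(v) == 1) v[[1]] else unlist(v))
  class(cfg) <- if (kind == "mtl") "lina_config" else "stl_config"
  params <- restore_params(obj$params, kind)
  list(params = params, config = cfg, kind = kind, extra = obj$extra)
}

# fromJSON leaves 1 x k weight matrices and scalars slightly mangled;
# coerce the parameter tree back to the shapes the engine expects
restore_params <- function(p, kind) {
  as_mat <- function(x, nr, nc) {
    if (is.matrix(x)) matrix(as.numeric(x), nr, nc)
    else matrix(as.numeric(unlist(x)), nr, nc, byrow = TRUE)
  }
  fix_net <- function(net, n_in, hidden, n_out) {
    sizes <- c(n_in, hidden)
    for (l in seq_along(net$hidden)) {
      net$hidden[[l]]$W <- as_mat(net$hidden[[l]]$W, sizes[l], sizes[l + 1])
      for (f in c("b", "gamma", "beta", "run_mean", "run_var")) {
        net$hidden[[l]][[f]] <- as.numeric(unlist(net$hidden[[l]][[f]]))
      }
    }
    net$out$W <- as_mat(net$out$W, sizes[length(sizes)], n_out)
    net$out$b <- as.numeric(unlist(net$out$b))
    net
  }
  if (kind == "mtl") {
    d <- length(unlist(p$B))
    p$K <- if (is.matrix(p$K)) {
      matrix(as.numeric(p$K), nrow(p$K), ncol(p$K))
    } else {
      matrix(as.numeric(unlist(p$K)), nrow = d, byrow = TRUE)
    }
    m <- ncol(p$K)
    hid <- vapply(p$attention$hidden, function(l) length(unlist(l$b)), 1L)
    p$attention <- fix_net(p$attention, m, hid, m)
    p$B <- as.numeric(unlist(p$B))
  } else {
    hid <- vapply(p$net$hidden, function(l) length(unlist(l$b)), 1L)
    n_in <- length(unlist(p$net$hidden[[1]]$W)) / hid[1]
    p$net <- fix_net(p$net, n_in, hid, 1L)
  }
  p
}
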