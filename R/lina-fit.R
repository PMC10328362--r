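#' Fit a multi-task linearizing neural network (MTL LINA)
#'
#' Trains the multi-task model \eqn{Y = S(K (A \circ X) + B)},
#' \eqn{A = F(X)}, on a genotype matrix and a binary multi-trait outcome
#' matrix: the cohort is split into train/validation/test subsets, the
#' model is trained by mini-batch Adam on the weighted cross-entropy loss
#' \eqn{W^T E + \beta\|K\|_2} with one checkpoint per epoch, and the
#' checkpoint with the best validation performance is kept as the fitted
#' model. All randomness (split, initialization, shuffling, dropout)
#' derives from \code{seed}, so refits are bit-reproducible.
#'
#' @param genotypes a [genotype_dataset()] (possibly file-backed) or an
#'   n x m matrix of 0/1/2 genotypes.
#' @param phenotypes a [phenotype_matrix()] or n x d binary matrix.
#' @param hidden three hidden-layer sizes of the attention subnetwork
#'   (default \code{c(1000, 250, 50)}).
#' @param dropout_rate,leaky_slope,penalty,loss_weights,squared_penalty
#'   architecture and loss settings, see [lina_config()].
#' @param epochs training epochs (default 100).
#' @param batch_size mini-batch size (default 512).
#' @param learning_rate Adam initial learning rate (default 1e-4).
#' @param split three train/validation/test fractions (default
#'   \code{c(0.70, 0.15, 0.15)}), or a ready-made [split_cohort()] object.
#' @param selection validation criterion for checkpoint choice:
#'   \code{"roc_auc"} (mean over traits, default) or \code{"loss"}.
#' @param seed integer seed.
#' @param checkpoint_dir optional directory; when given, every epoch's
#'   checkpoint is also persisted there as JSON.
#' @param keep_checkpoints keep all per-epoch parameter sets in the fitted
#'   object (memory permitting) instead of only the selected one.
#' @param verbose print per-epoch loss and validation metric.
#' @return An object of class \code{"lina"}: a list with the selected
#'   \code{params}, \code{best_epoch}, per-epoch \code{history}, the
#'   \code{split}, the \code{config}, trait/SNP annotation and (optionally)
#'   all \code{checkpoints}. Supported methods: \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{fitted},
#'   \code{residuals}, \code{plot}, \code{simulate}.
#' @examples
#' cfg <- sim_config(n_subjects = 300, n_snps = 40, n_traits = 2,
#'                   n_causal_per_trait = 5, prevalences = 0.2, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' fit <- lina(cohort$genotypes, cohort$phenotypes, hidden = c(16, 8, 4),
#'             epochs = 3, learning_rate = 1e-3, seed = 7)
#' fit
#' head(predict(fit, cohort$genotypes))
#' @export
lina <- function(genotypes, phenotypes, hidden = c(1000, 250, 50),
                 dropout_rate = 0.5, leaky_slope = 0.01, penalty = 1e-3,
                 loss_weights = NULL, squared_penalty = FALSE,
                 epochs = 100, batch_size = 512, learning_rate = 1e-4,
                 split = c(0.70, 0.15, 0.15),
                 selection = c("roc_auc", "loss"), seed = 1L,
                 checkpoint_dir = NULL, keep_checkpoints = FALSE,
                 verbose = FALSE) {
  selection <- match.arg(selection)
  dat <- align_training_data(genotypes, phenotypes)
  config <- lina_config(n_snps = dat$m, n_traits = dat$d, hidden = hidden,
                        dropout_rate = dropout_rate,
                        leaky_slope = leaky_slope, penalty = penalty,
                        loss_weights = loss_weights,
                        squared_penalty = squared_penalty)
  split <- resolve_split(split, dat$n, seed)
  params <- lina_init(config, seed = seed)
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  }
  tr <- train_loop(
    params, dat$genotypes, dat$Y, split$train, split$val,
    grad_fun = function(p, X, Yb) lina_grad(p, X, Yb, config),
    metric_fun = function(p, X, Yb) {
      validation_metric(p, X, Yb, config, "mtl", selection)
    },
    epochs = epochs, batch_size = batch_size,
    learning_rate = learning_rate, seed = seed + 1L,
    checkpoint_dir = checkpoint_dir,
    checkpoint_writer = function(p, path) {
      write_checkpoint(p, config, path, kind = "mtl")
    },
    verbose = verbose)
  best <- best_epoch_of(tr$history$val_metric)
  fit <- structure(
    list(params = tr$checkpoints[[best]], best_epoch = best,
         history = tr$history, split = split, config = config,
         trait_names = dat$trait_names, snp_ids = dat$snp_ids,
         is_decoy = dat$is_decoy, chromosomes = dat$chromosomes,
         seed = as.integer(seed),
         checkpoints = if (keep_checkpoints) tr$checkpoints else NULL,
         call = match.call()),
    class = "lina")
  fit
}

#' Fit the single-task feedforward baseline
#'
#' One binary trait, a plain three-hidden-layer feedforward net with a
#' sigmoid output, trained with binary cross-entropy under the same
#' split / optimizer / checkpoint-selection protocol as [lina()].
#'
#' @inheritParams lina
#' @param phenotype a binary vector of length n, or a
#'   \code{phenotype_matrix} together with \code{trait} naming the column.
#' @param trait trait name or index when \code{phenotype} is a matrix.
#' @return an object of class \code{"stl_net"} with the same components and
#'   methods as a \code{"lina"} fit (single trait).
#' @export
stl_net <- function(genotypes, phenotype, trait = 1L,
                    hidden = c(1000, 250, 50), dropout_rate = 0.5,
                    leaky_slope = 0.01, epochs = 100, batch_size = 512,
                    learning_rate = 1e-4, split = c(0.70, 0.15, 0.15),
                    selection = c("roc_auc", "loss"), seed = 1L,
                    checkpoint_dir = NULL, keep_checkpoints = FALSE,
                    verbose = FALSE) {
  selection <- match.arg(selection)
  if (inherits(phenotype, "phenotype_matrix")) {
    trait_name <- if (is.character(trait)) trait
                  else phenotype$trait_names[trait]
    y <- phenotype$outcomes[, trait_name]
  } else {
    y <- as.integer(phenotype)
    trait_name <- if (is.character(trait)) trait else "trait"
  }
  dat <- align_training_data(genotypes, matrix(y, ncol = 1,
                                               dimnames = list(NULL, trait_name)))
  config <- stl_config(n_snps = dat$m, hidden = hidden,
                       dropout_rate = dropout_rate,
                       leaky_slope = leaky_slope)
  split <- resolve_split(split, dat$n, seed)
  params <- stl_init(config, seed = seed)
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  }
  tr <- train_loop(
    params, dat$genotypes, dat$Y, split$train, split$val,
    grad_fun = function(p, X, Yb) stl_grad(p, X, Yb, config),
    metric_fun = function(p, X, Yb) {
      validation_metric(p, X, Yb, config, "stl", selection)
    },
    epochs = epochs, batch_size = batch_size,
    learning_rate = learning_rate, seed = seed + 1L,
    checkpoint_dir = checkpoint_dir,
    checkpoint_writer = function(p, path) {
      write_checkpoint(p, config, path, kind = "stl")
    },
    verbose = verbose)
  best <- best_epoch_of(tr$history$val_metric)
  structure(
    list(params = tr$checkpoints[[best]], best_epoch = best,
         history = tr$history, split = split, config = config,
         trait_names = trait_name, snp_ids = dat$snp_ids,
         is_decoy = dat$is_decoy, chromosomes = dat$chromosomes,
         seed = as.integer(seed),
         checkpoints = if (keep_checkpoints) tr$checkpoints else NULL,
         call = match.call()),
    class = "stl_net")
}

align_training_data <- function(genotypes, phenotypes) {
  if (inherits(phenotypes, "phenotype_matrix")) {
    Y <- phenotypes$outcomes
    trait_names <- phenotypes$trait_names
  } else {
    Y <- as.matrix(phenotypes)
    trait_names <- colnames(Y)
    if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(ncol(Y)))
  }
  if (!all(Y %in% c(0L, 1L))) stop("phenotypes must be binary 0/1")
  if (inherits(genotypes, "genotype_dataset")) {
    n <- n_subjects(genotypes)
    m <- n_snps(genotypes)
    snp_ids <- genotypes$snp_ids
    is_decoy <- genotypes$is_decoy
    chromosomes <- genotypes$chromosomes
    if (!is.null(genotypes$genotypes)) {
      # in-memory dataset: hand the trainer a double matrix once, instead
      # of converting every mini-batch (file-backed datasets stay lazy)
      g <- genotypes$genotypes
      storage.mode(g) <- "double"
      genotypes <- g
    }
  } else {
    genotypes <- as.matrix(genotypes)
    if (!is.double(genotypes)) storage.mode(genotypes) <- "double"
    n <- nrow(genotypes)
    m <- ncol(genotypes)
    snp_ids <- colnames(genotypes)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
    is_decoy <- rep(FALSE, m)
    chromosomes <- rep("1", m)
  }
  if (nrow(Y) != n) stop("genotypes and phenotypes disagree on n_subjects")
  list(genotypes = genotypes, Y = Y, n = n, m = m, d = ncol(Y),
       trait_names = trait_names, snp_ids = snp_ids, is_decoy = is_decoy,
       chromosomes = chromosomes)
}

resolve_split <- function(split, n, seed) {
  if (inherits(split, "cohort_split")) {
    if (total_split_n(split) != n) stop("split does not cover the cohort")
    return(split)
  }
  split_cohort(n, fractions = split, seed = seed)
}

# ---- methods --------------------------------------------------------------

#' @export
print.lina <- function(x, ...) {
  cat("Multi-task LINA model\n")
  cat(sprintf("  %d SNPs -> %s -> attention(%d) ; %d traits\n",
              x$config$n_snps, paste(x$config$hidden, collapse = "/"),
              x$config$n_snps, x$config$n_traits))
  cat(sprintf("  best epoch %d/%d (validation %s %.4f)\n", x$best_epoch,
              nrow(x$history), "metric",
              x$history$val_metric[x$best_epoch]))
  cat("  traits:", paste(utils::head(x$trait_names, 8), collapse = ", "),
      if (length(x$trait_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
print.stl_net <- function(x, ...) {
  cat(sprintf("Single-task baseline net (%s): %d SNPs -> %s -> 1\n",
              x$trait_names, x$config$n_snps,
              paste(x$config$hidden, collapse = "/")))
  cat(sprintf("  best epoch %d/%d (validation metric %.4f)\n", x$best_epoch,
              nrow(x$history), x$history$val_metric[x$best_epoch]))
  invisible(x)
}

#' Predict from a fitted LINA model
#'
#' @param object a fitted \code{"lina"} model.
#' @param newdata genotype matrix or \code{genotype_dataset}.
#' @param type \code{"response"} (probabilities), \code{"link"}
#'   (pre-sigmoid scores, the additive PRS scale) or \code{"attention"}
#'   (the attention vectors A).
#' @param ... unused.
#' @return n x d matrix (or n x m for attention) with dimnames.
#' @export
predict.lina <- function(object, newdata,
                         type = c("response", "link", "attention"), ...) {
  type <- match.arg(type)
  X <- as_input_matrix(newdata, object$config$n_snps)
  if (type == "attention") {
    A <- lina_attention(object$params, X, object$config, training = FALSE)
    colnames(A) <- object$snp_ids
    return(A)
  }
  fw <- lina_forward_full(object$params, X, object$config, training = FALSE)
  out <- if (type == "response") fw$prob else fw$score
  colnames(out) <- object$trait_names
  out
}

#' @export
predict.stl_net <- function(object, newdata,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- as_input_matrix(newdata, object$config$n_snps)
  fw <- mlp_forward(object$params$net, X, training = FALSE,
                    dropout = object$config$dropout_rate,
                    slope = object$config$leaky_slope)
  if (type == "response") as.vector(sigmoid(fw$out)) else as.vector(fw$out)
}

#' @export
coef.lina <- function(object, ...) {
  K <- object$params$K
  dimnames(K) <- list(object$trait_names, object$snp_ids)
  attr(K, "bias") <- stats::setNames(object$params$B, object$trait_names)
  K
}

#' @export
fitted.lina <- function(object, genotypes, ...) {
  predict(object, genotypes, type = "response")
}

#' Residuals of a fitted LINA model
#'
#' Response residuals \code{y - p} or Pearson residuals
#' \code{(y - p) / sqrt(p (1 - p))} on supplied data (the model does not
#' store its training genotypes).
#'
#' @param object fitted model.
#' @param genotypes,phenotypes evaluation data.
#' @param type \code{"response"} or \code{"pearson"}.
#' @param ... unused.
#' @export
residuals.lina <- function(object, genotypes, phenotypes,
                           type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  Y <- if (inherits(phenotypes, "phenotype_matrix")) phenotypes$outcomes
       else as.matrix(phenotypes)
  p <- predict(object, genotypes, type = "response")
  r <- Y - p
  if (type == "pearson") r <- r / sqrt(p * (1 - p))
  r
}

#' @export
summary.lina <- function(object, genotypes = NULL, phenotypes = NULL, ...) {
  out <- list(fit = object, metrics = NULL)
  if (!is.null(genotypes) && !is.null(phenotypes)) {
    out$metrics <- evaluate_metrics(object, genotypes, phenotypes)
  }
  class(out) <- "summary.lina"
  out
}

#' @export
print.summary.lina <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$metrics)) {
    cat("\nTest-set metrics (ROC baseline 0.5; PR baseline = prevalence):\n")
    print(as.data.frame(x$metrics), digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Training-history plot
#'
#' Training loss and validation metric per epoch, with the selected
#' checkpoint marked.
#'
#' @param x fitted \code{"lina"} or \code{"stl_net"} model.
#' @param ... graphics arguments passed on to [graphics::plot()].
#' @export
plot.lina <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "loss", ...)
  graphics::plot(h$epoch, h$val_metric, type = "l", xlab = "epoch",
                 ylab = "validation metric", main = "selection", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' @export
plot.stl_net <- plot.lina

#' Simulate outcomes from a fitted model
#'
#' Draws Bernoulli outcomes from the predicted per-trait probabilities,
#' e.g. for parametric-bootstrap checks.
#'
#' @param object fitted \code{"lina"} model.
#' @param nsim number of replicate outcome matrices.
#' @param seed optional integer seed.
#' @param genotypes genotypes to simulate outcomes for.
#' @param ... unused.
#' @return list of \code{nsim} binary n x d matrices.
#' @export
simulate.lina <- function(object, nsim = 1, seed = NULL, genotypes, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, genotypes, type = "response")
  lapply(seq_len(nsim), function(i) {
    y <- matrix(stats::rbinom(length(p), 1L, p), nrow(p), ncol(p))
    dimnames(y) <- dimnames(p)
    y
  })
}

#' Save a fitted model as a checkpoint file
#'
#' @param object fitted \code{"lina"} or \code{"stl_net"} model.
#' @param path JSON file path.
#' @return \code{path}, invisibly.
#' @export
save_model <- function(object, path) {
  kind <- if (inherits(object, "lina")) "mtl" else "stl"
  write_checkpoint(object$params, object$config, path, kind = kind,
                   extra = list(trait_names = object$trait_names,
                                snp_ids = object$snp_ids,
                                is_decoy = object$is_decoy,
                                chromosomes = object$chromosomes,
                                best_epoch = object$best_epoch,
                                seed = object$seed))
}

#' Load a fitted model from a checkpoint file
#'
#' @param path JSON checkpoint written by [save_model()] (or a per-epoch
#'   checkpoint from training, which carries no annotation).
#' @return a \code{"lina"} or \code{"stl_net"} object usable with
#'   \code{predict} and the interpretation functions.
#' @export
load_model <- function(path) {
  ck <- read_checkpoint(path)
  ex <- ck$extra
  g <- function(f, default) if (!is.null(ex[[f]])) unlist(ex[[f]]) else default
  m <- ck$config$n_snps
  obj <- list(params = ck$params, config = ck$config,
              best_epoch = g("best_epoch", NA_integer_),
              trait_names = g("trait_names",
                              if (ck$kind == "mtl")
                                paste0("trait", seq_len(ck$config$n_traits))
                              else "trait"),
              snp_ids = g("snp_ids", paste0("snp", seq_len(m))),
              is_decoy = as.logical(g("is_decoy", rep(FALSE, m))),
              chromosomes = as.character(g("chromosomes", rep("1", m))),
              seed = g("seed", NA_integer_),
              history = NULL, split = NULL, checkpoints = NULL)
  class(obj) <- if (ck$kind == "mtl") "lina" else "stl_net"
  obj
}
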