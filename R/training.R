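#' Random train/validation/test split of a cohort
#'
#' Seeded subject-level partition into training (70\%), validation (15\%)
#' and test (15\%) sets by default.
#'
#' @param n number of subjects.
#' @param fractions three fractions summing to 1.
#' @param seed integer seed.
#' @return object of class \code{"cohort_split"} with disjoint index
#'   vectors \code{train}, \code{val}, \code{test} covering \code{1:n}.
#' @export
split_cohort <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (n < 3) stop("need at least 3 subjects to split")
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3) {
    stop("fractions must be three numbers summing to 1")
  }
  set.seed(seed %% .Machine$integer.max)
  perm <- sample.int(n)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  if (n_train + n_val >= n) {  # guarantee a non-empty test set
    n_val <- max(1L, n - n_train - 1L)
  }
  structure(list(train = sort(perm[seq_len(n_train)]),
                 val = sort(perm[n_train + seq_len(n_val)]),
                 test = sort(perm[(n_train + n_val + 1):n]),
                 fractions = fractions, seed = as.integer(seed)),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("cohort_split: train %d / val %d / test %d (seed %d)\n",
              length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

#' ROC AUC by the rank statistic
#'
#' Mann-Whitney form with mid-rank tie handling, equivalent to the
#' trapezoidal area under the empirical ROC curve. Returns \code{NA} (with
#' a warning) when only one class is present, never a silent 0.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels.
#' @return AUC in \[0, 1\] or \code{NA}.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("ROC AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)  # mid-ranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' PR AUC by average precision
#'
#' Step-wise average precision over distinct score thresholds (tied scores
#' enter together), the conservative standard for imbalanced data;
#' trapezoidal interpolation of the PR curve is deliberately not used.
#' The no-skill baseline of a PR curve is the prevalence.
#'
#' @inheritParams roc_auc
#' @return average precision in \[0, 1\] or \code{NA} if no positives.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) {
    warning("PR AUC undefined: only one class present")
    return(NA_real_)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))        # last index of each tie group
  tp <- cumsum(y)[grp_end]
  pos_seen <- c(tp[1], diff(tp))
  prec <- tp / grp_end
  sum(pos_seen * prec) / n1
}

#' Per-trait test metrics for a fitted model
#'
#' ROC AUC (rank statistic), PR AUC (average precision), prevalence (the PR
#' baseline; the ROC baseline is always 0.5) and case counts on held-out
#' subjects. Traits with a single class in the evaluation set get \code{NA}
#' metrics and a warning rather than a silent zero.
#'
#' @param object a fitted [lina()] or [stl_net()] model (anything with a
#'   \code{predict} method returning probabilities), or a score matrix.
#' @param genotypes genotype data for the evaluated subjects.
#' @param phenotypes matching \code{phenotype_matrix} (or binary matrix).
#' @param subset optional subject indices (defaults to the model's test
#'   split when the model carries one and the data are the full cohort).
#' @return data.frame of class \code{"metrics_record"}: trait, n, n_case,
#'   prevalence, roc_auc, pr_auc.
#' @export
evaluate_metrics <- function(object, genotypes, phenotypes, subset = NULL) {
  Y <- if (inherits(phenotypes, "phenotype_matrix")) phenotypes$outcomes
       else as.matrix(phenotypes)
  traits <- colnames(Y)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(Y)))
  if (is.numeric(object)) {
    scores <- as.matrix(object)
  } else {
    X <- if (inherits(genotypes, "genotype_dataset")) genotypes else as.matrix(genotypes)
    if (is.null(subset) && !is.null(object$split) &&
        n_rows_of(X) == total_split_n(object$split)) {
      subset <- object$split$test
    }
    if (!is.null(subset)) {
      X <- if (inherits(X, "genotype_dataset")) fetch_genotypes(X, subset)
           else X[subset, , drop = FALSE]
      Y <- Y[subset, , drop = FALSE]
    }
    scores <- as.matrix(predict(object, X, type = "response"))
  }
  if (nrow(scores) != nrow(Y)) stop("scores and labels have different lengths")
  res <- data.frame(trait = traits,
                    n = nrow(Y),
                    n_case = colSums(Y),
                    prevalence = colMeans(Y),
                    roc_auc = NA_real_, pr_auc = NA_real_,
                    row.names = NULL)
  for (t in seq_along(traits)) {
    if (res$n_case[t] == 0 || res$n_case[t] == nrow(Y)) {
      warning("trait ", traits[t], ": single-class evaluation set, ",
              "metrics undefined")
      next
    }
    res$roc_auc[t] <- roc_auc(scores[, min(t, ncol(scores))], Y[, t])
    res$pr_auc[t] <- pr_auc(scores[, min(t, ncol(scores))], Y[, t])
  }
  class(res) <- c("metrics_record", "data.frame")
  res
}

n_rows_of <- function(X) {
  if (inherits(X, "genotype_dataset")) n_subjects(X) else nrow(X)
}

total_split_n <- function(split) {
  length(split$train) + length(split$val) + length(split$test)
}

#' Relative increase of over-baseline AUC gain
#'
#' The transfer metric: how much larger the multi-task model's AUC gain
#' over the no-skill baseline is than the single-task model's, in percent:
#' \deqn{\frac{(AUC_{MTL} - b) - (AUC_{STL} - b)}{AUC_{STL} - b} \times 100.}
#' Baselines are 0.5 (50 on the percent scale) for ROC AUC and the
#' prevalence for PR AUC. Undefined (an error) when the single-task AUC
#' equals the baseline, where the ratio blows up.
#'
#' @param model_auc AUC of the model of interest (fraction or percent, as
#'   long as all three arguments share a scale).
#' @param stl_auc AUC of the single-task comparator.
#' @param baseline no-skill baseline on the same scale.
#' @return relative increase in percent (vectorized).
#' @export
relative_increase <- function(model_auc, stl_auc, baseline) {
  if (any(stl_auc == baseline)) {
    stop("relative increase undefined: single-task AUC equals the baseline")
  }
  ((model_auc - baseline) - (stl_auc - baseline)) / (stl_auc - baseline) * 100
}

# ---- internal training loop ----------------------------------------------

# Shared by lina() and stl_net(). `grad_fun(params, X, Y)` returns
# list(loss, grads, params); `metric_fun(params, X, Y)` returns the
# validation selection metric (larger is better). Mini-batches are drawn
# from a seeded shuffle each epoch; genotype rows are fetched per batch so
# the full matrix is never required resident (file-backed datasets stream).
train_loop <- function(params, genotypes, Y, idx_train, idx_val,
                       grad_fun, metric_fun,
                       epochs, batch_size, learning_rate, seed,
                       checkpoint_dir = NULL, checkpoint_writer = NULL,
                       verbose = FALSE) {
  set.seed(seed %% .Machine$integer.max)
  state <- adam_init(params)
  history <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                        val_metric = NA_real_)
  checkpoints <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample(idx_train)
    batch_losses <- c()
    for (s in seq(1, length(perm), by = batch_size)) {
      rows <- perm[s:min(s + batch_size - 1, length(perm))]
      Xb <- fetch_rows(genotypes, rows)
      Yb <- Y[rows, , drop = FALSE]
      gr <- grad_fun(params, Xb, Yb)
      if (!is.finite(gr$loss)) {
        stop(sprintf("non-finite loss at epoch %d (batch starting %d); ",
                     ep, s),
             "lower the learning rate or check the inputs")
      }
      st <- adam_step(gr$params, gr$grads, state, lr = learning_rate)
      params <- st$params
      state <- st$state
      batch_losses <- c(batch_losses, gr$loss)
    }
    Xv <- fetch_rows(genotypes, idx_val)
    history$train_loss[ep] <- mean(batch_losses)
    history$val_metric[ep] <- metric_fun(params, Xv, Y[idx_val, , drop = FALSE])
    checkpoints[[ep]] <- params
    if (!is.null(checkpoint_dir)) {
      checkpoint_writer(params, file.path(checkpoint_dir,
                                          sprintf("epoch_%03d.json", ep)))
    }
    if (verbose) {
      message(sprintf("epoch %3d  loss %.5f  val %.5f", ep,
                      history$train_loss[ep], history$val_metric[ep]))
    }
  }
  list(checkpoints = checkpoints, history = history)
}

# argmax with earliest-tie rule; all-undefined metrics (e.g. a single-class
# validation set) fall back to the final epoch
best_epoch_of <- function(vals) {
  b <- which.max(vals)
  if (length(b) == 0) length(vals) else b
}

fetch_rows <- function(genotypes, rows) {
  X <- if (inherits(genotypes, "genotype_dataset")) {
    fetch_genotypes(genotypes, rows)
  } else {
    genotypes[rows, , drop = FALSE]
  }
  if (!is.double(X)) storage.mode(X) <- "double"
  X
}

#' Pick the checkpoint with the best validation performance
#'
#' Evaluates every checkpoint on the validation data and returns the argmax
#' of the selection metric; exact ties go to the earliest epoch.
#'
#' @param checkpoints list of parameter sets, one per epoch.
#' @param X_val,Y_val validation genotypes and outcomes.
#' @param config model config matching the checkpoints.
#' @param kind \code{"mtl"} or \code{"stl"}.
#' @param metric \code{"roc_auc"} (mean validation ROC AUC over traits,
#'   the default) or \code{"loss"} (negated, so larger is still better).
#' @return list with \code{params} and \code{epoch}.
#' @export
select_best_checkpoint <- function(checkpoints, X_val, Y_val, config,
                                   kind = c("mtl", "stl"),
                                   metric = c("roc_auc", "loss")) {
  kind <- match.arg(kind)
  metric <- match.arg(metric)
  if (length(checkpoints) == 0) stop("no checkpoints to select from")
  Y_val <- as.matrix(Y_val)
  vals <- vapply(checkpoints, function(p) {
    validation_metric(p, X_val, Y_val, config, kind, metric)
  }, 0)
  best <- which.max(vals)  # which.max takes the earliest maximum
  list(params = checkpoints[[best]], epoch = best, metric_value = vals[best])
}

validation_metric <- function(params, X, Y, config, kind, metric) {
  if (kind == "mtl") {
    p <- lina_forward(params, X, config, training = FALSE)
  } else {
    p <- matrix(stl_forward(params, X, config, training = FALSE))
  }
  if (metric == "loss") {
    return(-mean(vapply(seq_len(ncol(Y)),
                        function(t) mean(bce(p[, t], Y[, t])), 0)))
  }
  aucs <- vapply(seq_len(ncol(Y)), function(t) {
    if (length(unique(Y[, t])) < 2) return(NA_real_)
    roc_auc(p[, t], Y[, t])
  }, 0)
  mean(aucs, na.rm = TRUE)
}
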