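# Model-wise interpretation of a trained MTL LINA model. Because the model
# is exactly linear in X given the attention vector A, the instance-wise
# linear coefficient of trait t and SNP j at input x is K_tj * A_j(x) with
# no sampling approximation, and second-order (interaction) scores follow
# exactly from the Jacobian of A.

SEX_CHROMS <- c("X", "Y", "XY", "MT", "23", "24", "25", "26")

#' First-order model-wise SNP importance
#'
#' For each trait t and SNP j the instance-wise linear coefficient is
#' \eqn{c_{tj}(x) = K_{tj} A_j(x)} (exact, by the linearization identity).
#' The model-wise score aggregates over an interpretation cohort, by
#' default \eqn{s_{tj} = | \mathrm{mean}_x\, c_{tj}(x) |} (the absolute
#' value of a coherent model-wise linear coefficient); the alternative
#' \code{aggregate = "mean_abs"} uses \eqn{\mathrm{mean}_x |c_{tj}(x)|}.
#' Only SNPs on non-sex chromosomes are kept.
#'
#' @param object a fitted [lina()] model (eval mode is implied; importance
#'   is always computed with dropout off and batch-norm frozen).
#' @param genotypes interpretation genotypes; with a full-cohort dataset and
#'   a fitted split, the test subjects are used (the standard pipeline).
#' @param subset optional explicit subject indices into \code{genotypes}.
#' @param aggregate \code{"abs_mean"} (default) or \code{"mean_abs"}.
#' @param drop_sex_chromosomes drop X/Y/XY/MT columns (default TRUE).
#' @return object of class \code{"importance_table"}: list with
#'   \code{scores} (d x M nonnegative), \code{snp_ids}, \code{is_decoy},
#'   \code{chromosomes}, \code{trait_names}, \code{n_subjects_used},
#'   \code{aggregate}.
#' @export
model_importance <- function(object, genotypes, subset = NULL,
                             aggregate = c("abs_mean", "mean_abs"),
                             drop_sex_chromosomes = TRUE) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(object, "lina"))
  if (is.null(subset) && !is.null(object$split) &&
      n_rows_of(genotypes) == total_split_n(object$split)) {
    subset <- object$split$test
  }
  X <- fetch_rows(genotypes, if (is.null(subset)) seq_len(n_rows_of(genotypes))
                             else subset)
  A <- lina_attention(object$params, X, object$config, training = FALSE)
  K <- object$params$K
  scores <- if (aggregate == "abs_mean") {
    abs(K * rowrep(colMeans(A), nrow(K)))
  } else {
    abs(K) * rowrep(colMeans(abs(A)), nrow(K))
  }
  dimnames(scores) <- NULL
  keep <- rep(TRUE, ncol(scores))
  if (drop_sex_chromosomes) {
    keep <- !(toupper(object$chromosomes) %in% SEX_CHROMS)
  }
  structure(list(scores = scores[, keep, drop = FALSE],
                 snp_ids = object$snp_ids[keep],
                 is_decoy = object$is_decoy[keep],
                 chromosomes = object$chromosomes[keep],
                 trait_names = object$trait_names,
                 n_subjects_used = nrow(X),
                 aggregate = aggregate),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf(paste0("importance_table: %d traits x %d SNPs (%d decoy), ",
                     "%d subjects, aggregate=%s\n"),
              nrow(x$scores), ncol(x$scores), sum(x$is_decoy),
              x$n_subjects_used, x$aggregate))
  invisible(x)
}

#' Convert an importance table to a data.frame
#' @param x an \code{importance_table}.
#' @param ... unused.
#' @export
as.data.frame.importance_table <- function(x, ...) {
  df <- data.frame(snp_id = x$snp_ids, chromosome = x$chromosomes,
                   is_decoy = x$is_decoy, t(x$scores), check.names = FALSE)
  names(df)[-(1:3)] <- x$trait_names
  df
}

#' Jacobian of the attention vector at one input
#'
#' \eqn{J_{jk} = \partial A_j / \partial x_k}, exact for the eval-mode
#' network (piecewise linear) away from leaky-ReLU kinks: products of the
#' layer weight matrices with the batch-norm scale and the local
#' activation slopes.
#'
#' @param object fitted [lina()] model.
#' @param x a single genotype vector (length m).
#' @return m x m matrix with \code{J[j, k] = dA_j/dx_k}.
#' @export
attention_jacobian <- function(object, x) {
  stopifnot(inherits(object, "lina"))
  x <- as.numeric(x)
  if (length(x) != object$config$n_snps) stop("x must have length m")
  t(mlp_jacobian(object$params$attention, x,
                 slope = object$config$leaky_slope))
}

#' Second-order (interaction) scores for one trait
#'
#' For the pre-sigmoid output \eqn{z_i = \sum_j K_{ij} A_j(x) x_j + B_i}
#' the Hessian is exactly
#' \deqn{H^{(i)}_{kl} = K_{ik} J_{kl} + K_{il} J_{lk},}
#' because the attention map is piecewise linear (its second derivative
#' vanishes away from kinks). With multiple subjects the model-wise
#' interaction importance is the element-wise mean of \eqn{|H|}.
#'
#' @param object fitted [lina()] model.
#' @param X one genotype vector or a subject batch.
#' @param trait trait index or name.
#' @return object of class \code{"interaction_scores"}: an m x m symmetric
#'   matrix (\code{$scores}) plus metadata. For a single subject the signed
#'   Hessian is returned in \code{$hessian}.
#' @export
interaction_scores <- function(object, X, trait = 1L) {
  stopifnot(inherits(object, "lina"))
  if (is.character(trait)) trait <- match(trait, object$trait_names)
  X <- as_input_matrix(X, object$config$n_snps)
  Krow <- object$params$K[trait, ]
  acc <- NULL
  H1 <- NULL
  for (i in seq_len(nrow(X))) {
    J <- attention_jacobian(object, X[i, ])
    KJ <- Krow * J                       # row k scaled by K_{trait,k}
    H <- KJ + t(KJ)
    if (is.null(H1)) H1 <- H
    acc <- if (is.null(acc)) abs(H) else acc + abs(H)
  }
  structure(list(scores = acc / nrow(X),
                 hessian = if (nrow(X) == 1) H1 else NULL,
                 snp_ids = object$snp_ids,
                 trait = object$trait_names[trait],
                 n_subjects_used = nrow(X)),
            class = "interaction_scores")
}

#' Decoy-estimated FDR curve for one trait
#'
#' At every distinct importance score s (thresholds are inclusive: tied
#' SNPs enter together) the estimated FDR is the ratio of decoy to real
#' SNPs with score >= s — decoys carry no trait association, so decoys
#' above a threshold estimate the false discoveries among the reals above
#' it. No pseudocount is added by default; \code{pseudocount = TRUE} adds
#' +1 to the decoy count for conservative use.
#'
#' @param importance an [model_importance()] table containing decoys.
#' @param trait trait name or index.
#' @param pseudocount add 1 to the decoy count (default FALSE).
#' @return object of class \code{"fdr_curve"}: data.frame with descending
#'   \code{threshold}, \code{n_real_above}, \code{n_decoy_above},
#'   \code{fdr_estimate} (NA when no real SNP scores at the threshold).
#' @export
fdr_curve <- function(importance, trait = 1L, pseudocount = FALSE) {
  stopifnot(inherits(importance, "importance_table"))
  if (!any(importance$is_decoy)) {
    stop("importance table has no decoy SNPs; train on a decoy-augmented ",
         "dataset (see make_decoys)")
  }
  if (!any(!importance$is_decoy)) stop("importance table has no real SNPs")
  if (is.character(trait)) trait <- match(trait, importance$trait_names)
  s <- importance$scores[trait, ]
  dec <- importance$is_decoy
  thr <- sort(unique(s), decreasing = TRUE)
  # counts with score >= threshold, inclusive of ties
  n_real <- vapply(thr, function(t) sum(s >= t & !dec), 0L)
  n_dec <- vapply(thr, function(t) sum(s >= t & dec), 0L)
  if (length(thr) > 2000) {  # large tables: vectorized cumulative form
    o <- order(s, decreasing = TRUE)
    sr <- s[o]
    dr <- dec[o]
    last <- length(sr) - match(thr, rev(sr)) + 1L
    n_dec <- cumsum(dr)[last]
    n_real <- last - n_dec
  }
  fdr <- ifelse(n_real > 0, (n_dec + as.integer(pseudocount)) / n_real,
                NA_real_)
  out <- data.frame(threshold = thr, n_real_above = n_real,
                    n_decoy_above = n_dec, fdr_estimate = fdr)
  class(out) <- c("fdr_curve", "data.frame")
  attr(out, "trait") <- importance$trait_names[trait]
  out
}

#' Select important SNPs at a target FDR
#'
#' Chooses the smallest score threshold whose estimated FDR is at or below
#' \code{target_fdr} (maximizing the selected set; ties at the threshold
#' are all included) and returns the real SNPs at or above it. When no
#' threshold qualifies the selection is empty, with a warning.
#'
#' @param curve an [fdr_curve()] for the trait.
#' @param importance the matching importance table.
#' @param trait trait name or index (same trait as the curve).
#' @param target_fdr nominal FDR level, e.g. 0.001 or 0.05.
#' @return list with \code{snp_ids} (selected real SNPs, by descending
#'   score), \code{threshold}, \code{fdr_estimate} and counts.
#' @export
select_at_fdr <- function(curve, importance, trait = 1L, target_fdr) {
  stopifnot(inherits(curve, "fdr_curve"))
  ok <- which(!is.na(curve$fdr_estimate) & curve$fdr_estimate <= target_fdr)
  if (length(ok) == 0) {
    warning(sprintf("no importance threshold reaches FDR <= %g; empty set",
                    target_fdr))
    return(list(snp_ids = character(0), threshold = NA_real_,
                fdr_estimate = NA_real_, n_real = 0L, n_decoy = 0L))
  }
  pick <- ok[which.max(curve$n_real_above[ok])]  # smallest qualifying threshold
  thr <- curve$threshold[pick]
  if (is.character(trait)) trait <- match(trait, importance$trait_names)
  s <- importance$scores[trait, ]
  sel <- !importance$is_decoy & s >= thr
  ids <- importance$snp_ids[sel][order(s[sel], decreasing = TRUE)]
  list(snp_ids = ids, threshold = thr,
       fdr_estimate = curve$fdr_estimate[pick],
       n_real = curve$n_real_above[pick],
       n_decoy = curve$n_decoy_above[pick])
}

#' Pairwise (and optional 3-way) overlap of selected SNP sets
#'
#' @param selected_sets named list of per-trait SNP id vectors.
#' @param triples also return counts for every 3-trait intersection.
#' @return symmetric matrix of pairwise intersection counts (diagonal =
#'   set sizes); with \code{triples = TRUE}, a list with \code{pairs} and a
#'   data.frame \code{triples}.
#' @export
overlap_table <- function(selected_sets, triples = FALSE) {
  d <- length(selected_sets)
  if (d < 2) stop("need at least two traits")
  nm <- names(selected_sets)
  if (is.null(nm)) nm <- paste0("trait", seq_len(d))
  M <- matrix(0L, d, d, dimnames = list(nm, nm))
  for (a in seq_len(d)) {
    for (b in seq_len(d)) {
      M[a, b] <- length(intersect(selected_sets[[a]], selected_sets[[b]]))
    }
  }
  if (!triples) return(M)
  combs <- utils::combn(d, 3)
  tri <- data.frame(t(apply(combs, 2, function(idx) {
    c(idx, length(Reduce(intersect, selected_sets[idx])))
  })))
  names(tri) <- c("a", "b", "c", "n_common")
  tri$a <- nm[tri$a]; tri$b <- nm[tri$b]; tri$c <- nm[tri$c]
  list(pairs = M, triples = tri)
}

#' Genetic correlation between two traits' importance profiles
#'
#' Spearman rank correlation (mid-rank ties) between the two traits'
#' importance scores over the union of their FDR-selected SNP sets.
#'
#' @param importance an [model_importance()] table.
#' @param selected_sets named list of per-trait selected SNP ids (e.g. at
#'   5\% FDR).
#' @param trait_a,trait_b trait names or indices.
#' @return list with \code{rho}, \code{n_union}, \code{n_intersection};
#'   \code{rho} is \code{NA} (flagged by a warning) when the union has
#'   fewer than 2 SNPs.
#' @export
genetic_correlation <- function(importance, selected_sets, trait_a, trait_b) {
  ia <- if (is.character(trait_a)) match(trait_a, importance$trait_names) else trait_a
  ib <- if (is.character(trait_b)) match(trait_b, importance$trait_names) else trait_b
  na <- importance$trait_names[ia]
  nb <- importance$trait_names[ib]
  u <- union(selected_sets[[na]], selected_sets[[nb]])
  inter <- length(intersect(selected_sets[[na]], selected_sets[[nb]]))
  if (length(u) < 2) {
    warning("union of selected sets has fewer than 2 SNPs; rho undefined")
    return(list(rho = NA_real_, n_union = length(u), n_intersection = inter))
  }
  cols <- match(u, importance$snp_ids)
  rho <- stats::cor(importance$scores[ia, cols], importance$scores[ib, cols],
                    method = "spearman")
  list(rho = rho, n_union = length(u), n_intersection = inter)
}

#' All-pairs genetic-correlation report
#'
#' @param importance an [model_importance()] table.
#' @param selected_sets named list of per-trait selected SNP ids.
#' @return data.frame: trait_a, trait_b, n_union, n_intersection, spearman_rho.
#' @export
correlation_report <- function(importance, selected_sets) {
  nm <- names(selected_sets)
  pairs <- utils::combn(length(nm), 2)
  rows <- apply(pairs, 2, function(ab) {
    r <- suppressWarnings(
      genetic_correlation(importance, selected_sets, nm[ab[1]], nm[ab[2]]))
    data.frame(trait_a = nm[ab[1]], trait_b = nm[ab[2]],
               n_union = r$n_union, n_intersection = r$n_intersection,
               spearman_rho = r$rho)
  })
  do.call(rbind, rows)
}

#' Manhattan-style importance plot
#'
#' Importance scores of real (dark) and decoy (orange) SNPs for one trait,
#' with optional FDR threshold lines.
#'
#' @param x an \code{importance_table}.
#' @param trait trait name or index.
#' @param thresholds optional named numeric vector of score thresholds.
#' @param ... passed to [graphics::plot()].
#' @export
plot.importance_table <- function(x, trait = 1L, thresholds = NULL, ...) {
  if (is.character(trait)) trait <- match(trait, x$trait_names)
  s <- x$scores[trait, ]
  col <- ifelse(x$is_decoy, "darkorange", "grey25")
  graphics::plot(seq_along(s), s, col = col, pch = 16, cex = 0.5,
                 xlab = "SNP index", ylab = "importance score",
                 main = x$trait_names[trait], ...)
  if (!is.null(thresholds)) {
    graphics::abline(h = thresholds, lty = 2, col = "blue")
  }
  invisible(x)
}
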