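test_that("first-order importance is exact under constant attention and matches a brute-force oracle", {
  cfg <- lina_config(5, 2, hidden = c(3, 3, 2))
  a0 <- c(0.5, -2, 1, 0, 3)
  K <- matrix(rnorm(10), 2, 5)
  K[2, ] <- 0                       # a zero K row silences a trait entirely
  p <- constant_attention_params(cfg, a0, K, B = c(0, 0))
  fit <- as_lina_fit(p, cfg)
  X <- matrix(as.double(sample(0:2, 40, TRUE)), 8, 5)
  imp <- model_importance(fit, X)
  expect_equal(imp$scores[1, ], abs(K[1, ] * a0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(imp$scores[2, ] == 0))
  expect_true(all(imp$scores >= 0))
  expect_identical(imp$n_subjects_used, 8L)

  # brute-force oracle on a non-constant model: per-subject coefficients
  # K_tj * A_j(x), averaged, then abs (and the mean-abs alternative)
  p2 <- lina_init(cfg, seed = 5)
  fit2 <- as_lina_fit(p2, cfg)
  A <- lina_attention(p2, X, cfg)
  for (agg in c("abs_mean", "mean_abs")) {
    got <- model_importance(fit2, X, aggregate = agg)$scores
    want <- matrix(0, 2, 5)
    for (t in 1:2) for (j in 1:5) {
      cs <- vapply(1:8, function(i) p2$K[t, j] * A[i, j], 0)
      want[t, j] <- if (agg == "abs_mean") abs(mean(cs)) else mean(abs(cs))
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("sex-chromosome columns are excluded from importance tables", {
  cfg <- lina_config(6, 1, hidden = c(3, 2, 2))
  p <- lina_init(cfg, seed = 6)
  fit <- as_lina_fit(p, cfg,
                     chromosomes = c("1", "X", "22", "Y", "23", "MT"))
  X <- matrix(as.double(sample(0:2, 30, TRUE)), 5, 6)
  imp <- model_importance(fit, X)
  expect_identical(imp$snp_ids, c("snp1", "snp3"))
  imp_all <- model_importance(fit, X, drop_sex_chromosomes = FALSE)
  expect_identical(ncol(imp_all$scores), 6L)
})

test_that("the attention Jacobian is exact: zero for constant maps, the matrix for linear maps, FD elsewhere", {
  cfg <- lina_config(3, 1, hidden = c(3, 3, 3))
  p <- constant_attention_params(cfg, c(1, 2, 3), matrix(0, 1, 3), 0)
  fit <- as_lina_fit(p, cfg)
  expect_equal(attention_jacobian(fit, c(1, 0, 2)), matrix(0, 3, 3),
               ignore_attr = TRUE)

  # an exactly linear subnetwork: batch-norm tuned to identity, biases keep
  # every pre-activation positive, so A = x M1 M2 M3 Mo + const
  cfg2 <- lina_config(2, 1, hidden = c(2, 2, 2))
  p2 <- lina_init(cfg2, seed = 7)
  Ms <- list(matrix(c(0.3, -0.1, 0.2, 0.4), 2, 2),
             matrix(c(0.5, 0.1, -0.2, 0.3), 2, 2),
             matrix(c(0.2, 0.3, 0.1, -0.4), 2, 2))
  for (l in 1:3) {
    p2$attention$hidden[[l]]$W <- Ms[[l]]
    p2$attention$hidden[[l]]$b <- c(0, 0)
    p2$attention$hidden[[l]]$gamma <- c(1, 1)
    p2$attention$hidden[[l]]$beta <- c(10, 10)   # shifts into the linear region
    p2$attention$hidden[[l]]$run_mean <- c(0, 0)
    p2$attention$hidden[[l]]$run_var <- c(1, 1) - 1e-5
  }
  Mo <- matrix(c(0.4, -0.3, 0.1, 0.2), 2, 2)
  p2$attention$out$W <- Mo
  p2$attention$out$b <- c(0, 0)
  fit2 <- as_lina_fit(p2, cfg2)
  J <- attention_jacobian(fit2, c(1, 1))
  expect_equal(J, t(Ms[[1]] %*% Ms[[2]] %*% Ms[[3]] %*% Mo),
               tolerance = 1e-10)

  # random nets: central finite differences agree entrywise
  set.seed(71)
  for (i in 1:3) {
    cfg3 <- lina_config(4, 1, hidden = c(4, 3, 2))
    p3 <- lina_init(cfg3, seed = 70 + i)
    fit3 <- as_lina_fit(p3, cfg3)
    x <- runif(4, 0.1, 1.9)
    J3 <- attention_jacobian(fit3, x)
    for (j in 1:4) {
      fj <- function(v) lina_attention(p3, matrix(v, 1), cfg3)[1, j]
      expect_equal(J3[j, ], fd_grad(fj, x, h = 1e-4), tolerance = 1e-4,
                   ignore_attr = TRUE)
    }
  }
})

test_that("second-order scores equal the exact Hessian of the pre-sigmoid output", {
  # constant attention (J = 0): a purely linear model has no interactions
  cfg <- lina_config(3, 2, hidden = c(2, 2, 2))
  p <- constant_attention_params(cfg, c(1, 1, 1), matrix(rnorm(6), 2, 3),
                                 B = c(0, 0))
  fit <- as_lina_fit(p, cfg)
  ints <- interaction_scores(fit, c(1, 2, 0), trait = 1)
  expect_equal(ints$scores, matrix(0, 3, 3), ignore_attr = TRUE)

  # random nets, m <= 20: H_kl = K_ik J_kl + K_il J_lk matches the
  # finite-difference Hessian of z_i (exact away from kinks because z_i is
  # locally quadratic), and is symmetric by construction
  set.seed(91)
  for (i in 1:3) {
    m <- sample(c(5, 8, 12), 1)
    cfgr <- lina_config(m, 2, hidden = c(6, 5, 4))
    pr <- lina_init(cfgr, seed = 90 + i)
    fitr <- as_lina_fit(pr, cfgr)
    x <- runif(m, 0.1, 1.9)
    H <- interaction_scores(fitr, matrix(x, 1), trait = 2)$hessian
    expect_equal(H, t(H), tolerance = 1e-10)
    zfun <- function(v) {
      predict(fitr, matrix(v, 1), type = "link")[1, 2]
    }
    h <- 1e-3
    Hfd <- matrix(0, m, m)
    for (k in 1:m) for (l in 1:m) {
      ek <- el <- rep(0, m); ek[k] <- h; el[l] <- h
      Hfd[k, l] <- (zfun(x + ek + el) - zfun(x + ek - el) -
                      zfun(x - ek + el) + zfun(x - ek - el)) / (4 * h^2)
    }
    denom <- pmax(abs(Hfd), 1e-3)
    expect_lt(max(abs(H - Hfd) / denom), 1e-5)
  }
})

test_that("FDR estimates are decoy/real count ratios with inclusive thresholds", {
  cfg <- lina_config(8, 1, hidden = c(2, 2, 2))
  mk_imp <- function(real, decoy) {
    structure(list(scores = matrix(c(real, decoy), 1),
                   snp_ids = paste0("s", seq_along(c(real, decoy))),
                   is_decoy = c(rep(FALSE, length(real)),
                                rep(TRUE, length(decoy))),
                   chromosomes = rep("1", length(c(real, decoy))),
                   trait_names = "t1", n_subjects_used = 1L,
                   aggregate = "abs_mean"),
              class = "importance_table")
  }
  imp <- mk_imp(c(0.9, 0.8, 0.7, 0.2), c(0.75, 0.1, 0.05, 0.01))
  crv <- fdr_curve(imp, 1)
  expect_true(all(diff(crv$threshold) < 0))
  expect_true(all(diff(crv$n_real_above) >= 0))  # counts grow as threshold falls
  expect_equal(crv$fdr_estimate[crv$threshold == 0.7], 1 / 3)
  expect_equal(crv$fdr_estimate[crv$threshold == 0.9], 0)

  # all scores equal: one threshold, FDR = total decoys / total reals
  imp_eq <- mk_imp(rep(0.5, 4), rep(0.5, 2))
  crv_eq <- fdr_curve(imp_eq, 1)
  expect_identical(nrow(crv_eq), 1L)
  expect_equal(crv_eq$fdr_estimate, 0.5)

  no_dec <- mk_imp(c(0.9, 0.1), numeric(0))
  expect_error(fdr_curve(no_dec, 1), "make_decoys")
})

test_that("selection at a target FDR matches an exhaustive threshold-scan oracle", {
  mk_imp <- function(real, decoy) {
    structure(list(scores = matrix(c(real, decoy), 1),
                   snp_ids = paste0("s", seq_along(c(real, decoy))),
                   is_decoy = c(rep(FALSE, length(real)),
                                rep(TRUE, length(decoy))),
                   chromosomes = rep("1", length(c(real, decoy))),
                   trait_names = "t1", n_subjects_used = 1L,
                   aggregate = "abs_mean"),
              class = "importance_table")
  }
  # oracle: scan every distinct score as an inclusive threshold and take the
  # largest qualifying selection (the smallest qualifying threshold)
  oracle <- function(real, decoy, target) {
    s <- c(real, decoy)
    isd <- c(rep(FALSE, length(real)), rep(TRUE, length(decoy)))
    best <- integer(0)
    for (t in sort(unique(s), decreasing = TRUE)) {
      nr <- sum(s >= t & !isd); nd <- sum(s >= t & isd)
      if (nr > 0 && nd / nr <= target && nr > length(best)) {
        best <- which(!isd & s >= t)
      }
    }
    best
  }
  set.seed(101)
  for (i in 1:20) {
    real <- round(runif(12), 2)
    decoy <- round(runif(10), 2)
    target <- sample(c(0.1, 0.3, 0.5, 1), 1)
    imp <- mk_imp(real, decoy)
    crv <- fdr_curve(imp, 1)
    sel <- suppressWarnings(select_at_fdr(crv, imp, 1, target))
    o <- oracle(real, decoy, target)
    expect_setequal(sel$snp_ids,
                    if (length(o)) paste0("s", o) else character(0))
  }
  # vacuous bound selects every real SNP
  imp <- mk_imp(c(0.9, 0.8, 0.7, 0.2), c(0.75, 0.1, 0.05, 0.01))
  crv <- fdr_curve(imp, 1)
  expect_length(select_at_fdr(crv, imp, 1, 1)$snp_ids, 4)
  # adversarial: all decoys outscore all reals -> empty set with warning
  imp2 <- mk_imp(c(0.1, 0.2), c(0.8, 0.9))
  crv2 <- fdr_curve(imp2, 1)
  expect_warning(sel2 <- select_at_fdr(crv2, imp2, 1, 0.05), "empty")
  expect_length(sel2$snp_ids, 0)
})

test_that("overlap tables match brute-force set arithmetic, including 3-way intersections", {
  sets <- list(a = c("a", "b", "c"), b = c("b", "c", "d"))
  M <- overlap_table(sets)
  expect_equal(M["a", "b"], 2, ignore_attr = TRUE)
  expect_equal(M["a", "a"], 3, ignore_attr = TRUE)
  expect_identical(M, t(M))

  set.seed(111)
  universe <- paste0("snp", 1:1000)
  r <- list(x = sample(universe, 25), y = sample(universe, 36),
            z = sample(universe, 48))
  res <- overlap_table(r, triples = TRUE)
  expect_equal(res$triples$n_common,
               length(intersect(intersect(r$x, r$y), r$z)))
  expect_equal(res$pairs["x", "z"], length(intersect(r$x, r$z)),
               ignore_attr = TRUE)
  expect_error(overlap_table(list(a = "s1")), "at least two")
})

test_that("genetic correlation is Spearman over the union of selected sets", {
  imp <- structure(list(
    scores = rbind(c(5, 4, 3, 2, 1, 0.5), c(0.5, 1, 2, 3, 4, 5)),
    snp_ids = paste0("s", 1:6), is_decoy = rep(FALSE, 6),
    chromosomes = rep("1", 6), trait_names = c("t1", "t2"),
    n_subjects_used = 1L, aggregate = "abs_mean"),
    class = "importance_table")
  sets <- list(t1 = paste0("s", 1:4), t2 = paste0("s", 3:6))
  r <- genetic_correlation(imp, sets, "t1", "t2")
  expect_equal(r$n_union, 6)
  expect_equal(r$n_intersection, 2)
  expect_equal(r$rho, -1)   # exactly reversed ranks
  same <- genetic_correlation(imp, list(t1 = imp$snp_ids, t2 = imp$snp_ids),
                              "t1", "t1")
  expect_equal(same$rho, 1)

  # hand example with ties vs rank-then-Pearson brute force
  imp$scores <- rbind(c(1, 2, 2, 4, 7, 3), c(2, 1, 5, 5, 6, 4))
  r2 <- genetic_correlation(imp, sets, "t1", "t2")
  expect_equal(r2$rho,
               cor(rank(imp$scores[1, ]), rank(imp$scores[2, ])),
               tolerance = 1e-12)
  expect_warning(
    genetic_correlation(imp, list(t1 = "s1", t2 = "s1"), "t1", "t2"),
    "fewer than 2")
})
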