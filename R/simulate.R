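#' Simulation configuration for synthetic cohorts
#'
#' Describes a synthetic genotype/phenotype cohort: independent biallelic
#' SNPs in Hardy-Weinberg proportions, sparse additive liabilities per
#' trait, a tunable fraction of causal SNPs shared across traits
#' (pleiotropy) and low-prevalence binary outcomes from a
#' liability-threshold model.
#'
#' @param n_subjects number of subjects.
#' @param n_snps number of (real) SNPs.
#' @param n_traits number of binary traits.
#' @param n_causal_per_trait causal SNPs per trait.
#' @param shared_fraction fraction in \[0, 1\] of each trait's causal SNPs
#'   drawn from a single pleiotropic pool common to all traits.
#' @param heritability liability-scale heritability in \[0, 1).
#' @param prevalences per-trait case prevalences in (0, 1); recycled to
#'   \code{n_traits}.
#' @param maf_range minor-allele-frequency range, a sub-interval of (0, 0.5].
#' @param seed integer seed; every generator in this file is bit-reproducible
#'   given the seed (stage seeds are derived as documented fixed offsets).
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_subjects, n_snps, n_traits,
                       n_causal_per_trait = 20L,
                       shared_fraction = 0.8,
                       heritability = 0.5,
                       prevalences = 0.05,
                       maf_range = c(0.05, 0.5),
                       seed = 1L) {
  if (n_subjects < 1 || n_snps < 1) stop("n_subjects and n_snps must be >= 1")
  if (n_causal_per_trait > n_snps) stop("n_causal_per_trait exceeds n_snps")
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must be in [0, 1]")
  }
  if (heritability < 0 || heritability >= 1) {
    stop("heritability must be in [0, 1)")
  }
  prevalences <- rep_len(prevalences, n_traits)
  if (any(prevalences <= 0 | prevalences >= 1)) {
    stop("prevalences must be in (0, 1)")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must be a sub-interval of (0, 0.5]")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_snps = as.integer(n_snps),
                 n_traits = as.integer(n_traits),
                 n_causal_per_trait = as.integer(n_causal_per_trait),
                 shared_fraction = shared_fraction,
                 heritability = heritability,
                 prevalences = prevalences,
                 maf_range = maf_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# stage seeds derived from the config seed by fixed offsets, so adding a
# stage never perturbs the randomness of earlier stages
sim_seed <- function(config, stage) {
  offs <- c(genotypes = 0L, effects = 104729L, phenotypes = 224737L,
            decoys = 350377L)
  (config$seed + offs[[stage]]) %% .Machine$integer.max
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' SNP j gets a minor-allele frequency drawn uniformly from
#' \code{maf_range}; genotypes are sampled i.i.d. per subject with
#' P(0) = p^2, P(1) = 2p(1-p), P(2) = (1-p)^2 under the
#' homozygous-minor = 0 convention. SNPs are assigned round-robin to
#' autosomes 1..22 (so downstream non-sex-chromosome filters are exercised);
#' there is no linkage disequilibrium between SNPs.
#'
#' @param config a [sim_config()].
#' @return a [genotype_dataset()]; the drawn frequencies are kept in the
#'   \code{maf} field.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  m <- config$n_snps
  set.seed(sim_seed(config, "genotypes"))
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  # minor-allele count per subject is Binomial(2, p); code = 2 - count
  g <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    g[, j] <- 2L - stats::rbinom(n, 2L, maf[j])
  }
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, m, replace = TRUE)
  a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1), "")
  ds <- genotype_dataset(
    g,
    snp_ids = sprintf("snp%05d", seq_len(m)),
    chromosomes = as.character(rep_len(1:22, m)),
    positions = 1000L * seq_len(m),
    alleles = cbind(minor = a1, major = unname(a2)),
    sample_ids = sprintf("subj%06d", seq_len(n)))
  ds$maf <- maf
  ds
}

#' Simulate sparse per-trait liability effects with pleiotropy
#'
#' A pleiotropic pool of \code{round(shared_fraction * n_causal_per_trait)}
#' SNPs is drawn once and used by every trait; each trait fills the rest of
#' its causal set privately from the remaining SNPs. Nonzero effects are
#' Normal(0, heritability / n_causal_per_trait) per standardized genotype,
#' so the genetic liability variance is the heritability.
#'
#' @param config a [sim_config()].
#' @return an object of class \code{"effect_matrix"} with \code{betas}
#'   (d x m) and \code{causal_mask} (d x m logical).
#' @export
simulate_effects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_snps
  d <- config$n_traits
  k <- config$n_causal_per_trait
  n_shared <- round(config$shared_fraction * k)
  if (n_shared > m) stop("shared pool larger than the SNP panel")
  set.seed(sim_seed(config, "effects"))
  pool <- sample.int(m, n_shared)
  betas <- matrix(0, d, m)
  mask <- matrix(FALSE, d, m)
  sd_beta <- sqrt(config$heritability / k)
  for (t in seq_len(d)) {
    private <- sample(setdiff(seq_len(m), pool), k - n_shared)
    causal <- c(pool, private)
    mask[t, causal] <- TRUE
    b <- stats::rnorm(k, 0, sd_beta)
    # rescale so the realized genetic variance (sum of squared effects on
    # standardized genotypes) is exactly the heritability; otherwise the
    # chi-square spread of sum(b^2) makes prevalences drift off target
    if (config$heritability > 0) {
      b <- b * sqrt(config$heritability / sum(b^2))
    }
    betas[t, causal] <- b
  }
  structure(list(betas = betas, causal_mask = mask,
                 shared_pool = sort(pool)),
            class = "effect_matrix")
}

#' Simulate binary traits from a liability-threshold model
#'
#' Liability for trait t is \code{L_t = sum_j beta_tj z_j + eps}, with
#' \code{z_j} the column-standardized genotype and
#' \code{eps ~ Normal(0, 1 - heritability)}; a subject is a case for trait t
#' iff \code{L_t} exceeds the standard-normal quantile of
#' \code{1 - prevalence_t}.
#'
#' @param genotypes a \code{genotype_dataset}.
#' @param effects an \code{effect_matrix} from [simulate_effects()].
#' @param config the same [sim_config()] used upstream.
#' @return a [phenotype_matrix()]; the latent liabilities are kept in the
#'   \code{liability} field for oracle checks.
#' @export
simulate_phenotypes <- function(genotypes, effects, config) {
  stopifnot(inherits(config, "sim_config"))
  g <- fetch_genotypes(genotypes)
  if (ncol(g) != ncol(effects$betas)) stop("genotype/effect dimension mismatch")
  z <- scale(g)
  z[, attr(z, "scaled:scale") == 0] <- 0
  set.seed(sim_seed(config, "phenotypes"))
  d <- config$n_traits
  genetic <- z %*% t(effects$betas)                       # n x d
  eps_sd <- sqrt(1 - config$heritability)
  liab <- genetic + matrix(stats::rnorm(nrow(g) * d, 0, eps_sd), nrow(g), d)
  thresh <- stats::qnorm(1 - config$prevalences)
  y <- sweep(liab, 2, thresh, `>`) * 1L
  ph <- phenotype_matrix(y, trait_names = sprintf("trait%02d", seq_len(d)),
                         sample_ids = genotypes$sample_ids)
  ph$liability <- liab
  ph
}

#' Simulate a full cohort
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_effects()] and [simulate_phenotypes()].
#'
#' @param config a [sim_config()].
#' @return list with \code{genotypes}, \code{effects}, \code{phenotypes}.
#' @export
simulate_cohort <- function(config) {
  genotypes <- simulate_genotypes(config)
  effects <- simulate_effects(config)
  phenotypes <- simulate_phenotypes(genotypes, effects, config)
  list(genotypes = genotypes, effects = effects, phenotypes = phenotypes)
}

#' Append decoy SNPs with matched genotype frequencies
#'
#' For every real SNP j a decoy column is added whose genotypes are sampled
#' i.i.d. per subject from SNP j's *empirical* genotype distribution, so
#' decoys have the same observed frequencies of homozygous-minor,
#' heterozygous and homozygous-major genotypes but, being freshly sampled,
#' no association with any trait. The output holds all real SNPs followed by
#' their decoys (2m columns); decoy j inherits real SNP j's chromosome label
#' so the non-sex-chromosome filter treats the pair alike.
#'
#' @param genotypes a \code{genotype_dataset} without decoys.
#' @param seed integer seed.
#' @return a \code{genotype_dataset} with \code{2 * n_snps} columns and
#'   \code{is_decoy} set.
#' @export
make_decoys <- function(genotypes, seed = 1L) {
  if (any(genotypes$is_decoy)) {
    stop("dataset already contains decoy SNPs")
  }
  g <- fetch_genotypes(genotypes)
  n <- nrow(g)
  m <- ncol(g)
  set.seed(seed %% .Machine$integer.max)
  dec <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    freq <- tabulate(g[, j] + 1L, nbins = 3L) / n
    dec[, j] <- sample(0:2, n, replace = TRUE, prob = freq)
  }
  genotype_dataset(
    cbind(g, dec),
    snp_ids = c(genotypes$snp_ids, paste0(genotypes$snp_ids, "_decoy")),
    chromosomes = c(genotypes$chromosomes, genotypes$chromosomes),
    positions = c(genotypes$positions, genotypes$positions),
    alleles = rbind(genotypes$alleles, genotypes$alleles),
    sample_ids = genotypes$sample_ids,
    is_decoy = c(rep(FALSE, m), rep(TRUE, m)))
}
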