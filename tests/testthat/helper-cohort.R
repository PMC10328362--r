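# shared fixture builders; everything is generated in code at test time

# small random genotype dataset (no phenotypes)
random_dataset <- function(n, m, seed = 1) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  genotype_dataset(
    g,
    snp_ids = sprintf("rs%04d", seq_len(m)),
    chromosomes = as.character(rep_len(1:22, m)),
    positions = seq_len(m) * 100L,
    alleles = cbind(minor = rep("A", m), major = rep("G", m)),
    sample_ids = sprintf("s%03d", seq_len(n)))
}

# MTL parameters whose attention map is the constant vector a0:
# all hidden weights/biases zero (batch-norm identity on zeros), output
# layer bias = a0
constant_attention_params <- function(config, a0, K, B, seed = 1) {
  p <- lina_init(config, seed = seed)
  for (l in seq_along(p$attention$hidden)) {
    p$attention$hidden[[l]]$W[] <- 0
    p$attention$hidden[[l]]$b[] <- 0
  }
  p$attention$out$W[] <- 0
  p$attention$out$b <- a0
  p$K <- K
  p$B <- B
  p
}

# wrap raw params in a minimal fitted-model shell so interpretation
# functions (which take a fitted model) can run on hand-built parameters
as_lina_fit <- function(params, config,
                        snp_ids = paste0("snp", seq_len(config$n_snps)),
                        chromosomes = rep("1", config$n_snps),
                        is_decoy = rep(FALSE, config$n_snps)) {
  structure(list(params = params, config = config,
                 trait_names = paste0("trait", seq_len(config$n_traits)),
                 snp_ids = snp_ids, chromosomes = chromosomes,
                 is_decoy = is_decoy, split = NULL, history = NULL),
            class = "lina")
}

# independent PLINK .bed decoder used as a cross-check oracle: bit
# arithmetic per byte, no shared code with the package reader
oracle_read_bed <- function(path, n, m) {
  raw_all <- readBin(path, "raw", file.size(path))
  stopifnot(identical(as.integer(raw_all[1:3]), c(108L, 27L, 1L)))
  body <- as.integer(raw_all[-(1:3)])
  bpsnp <- ceiling(n / 4)
  out <- matrix(NA_integer_, n, m)
  code_map <- c(`0` = 0L, `1` = NA, `2` = 1L, `3` = 2L)
  for (j in seq_len(m)) {
    bytes <- body[(j - 1) * bpsnp + seq_len(bpsnp)]
    for (i in seq_len(n)) {
      byte <- bytes[(i - 1) %/% 4 + 1]
      code <- bitwAnd(bitwShiftR(byte, 2L * ((i - 1) %% 4)), 3L)
      out[i, j] <- code_map[[as.character(code)]]
    }
  }
  out
}

# central finite-difference gradient of f at x (vector in, scalar out)
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}
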