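# PLINK1 binary trio (.bed/.bim/.fam) codec.
#
# .bed layout: 3 magic bytes 0x6C 0x1B 0x01 (SNP-major), then for each SNP
# ceil(n/4) bytes, 4 subjects per byte, low-order bits first. Two-bit codes:
#   00 homozygous A1, 01 missing, 10 heterozygous, 11 homozygous A2.
# We write the minor allele as A1 (.bim column 5), so the codes map directly
# onto the in-memory convention 0 = hom minor, 1 = het, 2 = hom major.
# Trailing bits of the last byte per SNP are zero padding and ignored.

PLINK_MAGIC <- as.raw(c(0x6C, 0x1B, 0x01))

# 256 x 4 lookup: genotype of the k-th subject packed in a byte value;
# NA marks the missing code 01.
plink_lut <- local({
  codes <- c(0L, NA_integer_, 1L, 2L)
  lut <- matrix(NA_integer_, 256, 4)
  for (b in 0:255) {
    lut[b + 1, ] <- codes[bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L) + 1L]
  }
  lut
})

#' Read a PLINK1 binary genotype fileset
#'
#' Reads \code{prefix.bed}, \code{prefix.bim} and \code{prefix.fam} into a
#' [genotype_dataset()]. The .bim A1 allele is taken as the minor allele, so
#' PLINK's two-bit codes map onto the 0 = homozygous-minor / 1 = het /
#' 2 = homozygous-major convention used throughout the package.
#'
#' Missing genotypes (PLINK code 01) are handled per \code{missing}:
#' \code{"impute"} (default) replaces them with the SNP's modal genotype,
#' \code{"strict"} raises an error.
#'
#' With \code{lazy = TRUE} only the packed bytes are held and rows are
#' decoded on demand by [fetch_genotypes()]/[subject_blocks()], so cohorts
#' larger than memory (as a decoded double matrix) can be consumed in
#' subject blocks.
#'
#' @param prefix path stem of the fileset.
#' @param missing missing-genotype policy, \code{"impute"} or \code{"strict"}.
#' @param lazy decode on demand instead of materializing the matrix.
#' @return a \code{genotype_dataset}; \code{is_decoy} is all-\code{FALSE}
#'   for data loaded from disk.
#' @export
read_plink <- function(prefix, missing = c("impute", "strict"),
                       lazy = FALSE) {
  missing <- match.arg(missing)
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  ok <- file.exists(paths)
  if (!all(ok)) stop("missing PLINK file(s): ", paste(paths[!ok], collapse = ", "))

  bim <- utils::read.table(paths[2], header = FALSE, sep = "",
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"),
                           stringsAsFactors = FALSE)
  fam <- utils::read.table(paths[3], header = FALSE, sep = "",
                           stringsAsFactors = FALSE)
  m <- nrow(bim)
  n <- nrow(fam)
  bpsnp <- ceiling(n / 4)

  raw_all <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw_all) < 3 || !identical(raw_all[1:3], PLINK_MAGIC)) {
    stop("not a SNP-major PLINK1 .bed file (bad magic bytes): ", paths[1])
  }
  if (length(raw_all) != 3 + m * bpsnp) {
    stop(sprintf(".bed size %d != expected 3 + %d * %d", length(raw_all),
                 m, bpsnp))
  }
  bytes <- matrix(raw_all[-(1:3)], nrow = bpsnp, ncol = m)

  backend <- list(bytes = bytes, n = n, m = m, policy = missing)
  # per-SNP genotype counts (padding excluded) for imputation + strictness
  counts <- plink_column_counts(backend)
  if (missing == "strict" && any(counts$n_missing > 0)) {
    stop(sum(counts$n_missing), " missing genotype call(s) under strict policy")
  }
  if (any(counts$n_missing == n)) {
    stop("SNP(s) with no called genotypes cannot be imputed")
  }
  backend$impute_value <- counts$mode
  snp_ids <- bim[[2]]
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids in .bim")
  alleles <- cbind(minor = bim[[5]], major = bim[[6]])
  sample_ids <- as.character(fam[[2]])

  geno <- if (lazy) NULL else plink_decode_rows(backend, seq_len(n))
  genotype_dataset(geno, snp_ids = snp_ids, chromosomes = bim[[1]],
                   positions = bim[[4]], alleles = alleles,
                   sample_ids = sample_ids,
                   backend = if (lazy) backend else NULL)
}

# decode arbitrary subject rows from a packed-bytes backend
plink_decode_rows <- function(backend, rows) {
  byte_rows <- unique((rows - 1L) %/% 4L + 1L)
  sub <- backend$bytes[byte_rows, , drop = FALSE]
  dec <- plink_lut[as.integer(sub) + 1L, , drop = FALSE]  # (B*m) x 4
  v <- t(dec)
  dim(v) <- c(4L * length(byte_rows), backend$m)
  pos <- match((rows - 1L) %/% 4L + 1L, byte_rows)
  g <- v[(pos - 1L) * 4L + (rows - 1L) %% 4L + 1L, , drop = FALSE]
  if (anyNA(g)) {
    if (backend$policy == "strict") stop("missing genotype under strict policy")
    na_idx <- which(is.na(g), arr.ind = TRUE)
    g[na_idx] <- backend$impute_value[na_idx[, 2]]
  }
  g
}

# per-SNP genotype/missing counts from packed bytes, excluding pad bits;
# chunked over SNP columns so lazy loads never decode the whole matrix
plink_column_counts <- function(backend, chunk = 1024L) {
  n <- backend$n
  bpsnp <- nrow(backend$bytes)
  tab <- matrix(0L, backend$m, 4)
  for (s in seq(1L, backend$m, by = chunk)) {
    cols <- s:min(s + chunk - 1L, backend$m)
    dec <- plink_lut[as.integer(backend$bytes[, cols, drop = FALSE]) + 1L, ,
                     drop = FALSE]
    v <- t(dec)
    dim(v) <- c(4L * bpsnp, length(cols))
    v <- v[seq_len(n), , drop = FALSE]
    for (k in 0:2) tab[cols, k + 1] <- colSums(v == k, na.rm = TRUE)
    tab[cols, 4] <- colSums(is.na(v))
  }
  list(mode = max.col(tab[, 1:3, drop = FALSE], ties.method = "first") - 1L,
       n_missing = tab[, 4])
}

#' Write a genotype dataset as a PLINK1 binary fileset
#'
#' Emits \code{prefix.bed} (SNP-major), \code{prefix.bim} and
#' \code{prefix.fam} readable by [read_plink()] and by external PLINK tools.
#' The minor allele is written as A1. The .bed file is exactly
#' \code{3 + m * ceiling(n/4)} bytes.
#'
#' @param dataset a fully materialized \code{genotype_dataset}.
#' @param prefix output path stem.
#' @return \code{prefix}, invisibly.
#' @export
write_plink <- function(dataset, prefix) {
  g <- fetch_genotypes(dataset)
  n <- nrow(g)
  m <- ncol(g)
  bpsnp <- ceiling(n / 4)
  bitcode <- c(0L, 2L, 3L)[g + 1L]        # genotype -> two-bit code
  dim(bitcode) <- dim(g)
  padded <- matrix(0L, 4 * bpsnp, m)
  padded[seq_len(n), ] <- bitcode
  dim(padded) <- c(4L, bpsnp * m)
  bytes <- padded[1, ] + 4L * padded[2, ] + 16L * padded[3, ] + 64L * padded[4, ]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(PLINK_MAGIC, con)
  writeBin(as.raw(bytes), con)

  bim <- data.frame(chrom = dataset$chromosomes, id = dataset$snp_ids,
                    cm = 0, pos = dataset$positions,
                    a1 = dataset$alleles[, 1], a2 = dataset$alleles[, 2])
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = dataset$sample_ids, iid = dataset$sample_ids,
                    pat = 0, mat = 0, sex = 0, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
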