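#' Genotype dataset container
#'
#' Bundles a subjects x SNPs genotype matrix with its SNP and sample metadata.
#' Genotypes use the minor-allele-homozygote = 0 convention: 0 = homozygous
#' for the minor allele, 1 = heterozygous, 2 = homozygous for the major
#' allele. A dataset can be fully in memory or lazily backed by a PLINK1
#' \code{.bed} file (see [read_plink()] with \code{lazy = TRUE}), in which
#' case subject blocks are decoded on demand via [fetch_genotypes()].
#'
#' @param genotypes integer matrix (subjects x SNPs) with entries in
#'   \{0, 1, 2\}, or \code{NULL} for a file-backed dataset.
#' @param snp_ids unique SNP identifiers (length m).
#' @param chromosomes chromosome labels (length m); kept as character so
#'   non-autosomal codes ("X", "Y", "XY", "MT") survive round trips.
#' @param positions base-pair positions (length m).
#' @param alleles m x 2 character matrix, columns \code{minor}, \code{major}.
#' @param sample_ids unique subject identifiers (length n).
#' @param is_decoy logical length m; decoy columns are only ever created by
#'   [make_decoys()], never present in data loaded from disk.
#' @param backend internal; list describing a lazy PLINK backing store.
#' @return An object of class \code{"genotype_dataset"}.
#' @seealso [read_plink()], [write_plink()], [make_decoys()]
#' @export
genotype_dataset <- function(genotypes, snp_ids, chromosomes, positions,
                             alleles, sample_ids, is_decoy = NULL,
                             backend = NULL) {
  m <- length(snp_ids)
  n <- length(sample_ids)
  if (is.null(is_decoy)) is_decoy <- rep(FALSE, m)
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(chromosomes) != m || length(positions) != m ||
      length(is_decoy) != m) {
    stop("SNP metadata lengths disagree with snp_ids")
  }
  if (!is.matrix(alleles) || nrow(alleles) != m || ncol(alleles) != 2) {
    stop("alleles must be an m x 2 matrix (minor, major)")
  }
  if (!is.null(genotypes)) {
    genotypes <- as.matrix(genotypes)
    if (nrow(genotypes) != n || ncol(genotypes) != m) {
      stop("genotype matrix must be n_subjects x n_snps")
    }
    check_geno_codes(genotypes)
    storage.mode(genotypes) <- "integer"
    dimnames(genotypes) <- NULL
  } else if (is.null(backend)) {
    stop("either genotypes or a lazy backend must be supplied")
  }
  structure(
    list(genotypes = genotypes,
         snp_ids = as.character(snp_ids),
         chromosomes = as.character(chromosomes),
         positions = as.integer(positions),
         alleles = alleles,
         sample_ids = as.character(sample_ids),
         is_decoy = as.logical(is_decoy),
         backend = backend),
    class = "genotype_dataset")
}

check_geno_codes <- function(g) {
  bad <- !(g %in% c(0L, 1L, 2L))
  if (any(bad)) {
    stop("genotype entries must be 0, 1 or 2 (found ",
         paste(unique(g[bad])[1:min(3, sum(bad))], collapse = ", "), ")")
  }
  invisible(TRUE)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d subjects x %d SNPs (%d decoy)%s\n",
              n_subjects(x), n_snps(x), sum(x$is_decoy),
              if (is.null(x$genotypes)) " [file-backed]" else ""))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) c(n_subjects(x), n_snps(x))

#' Number of subjects / SNPs in a dataset
#' @param x a \code{genotype_dataset}.
#' @return integer count.
#' @export
n_subjects <- function(x) length(x$sample_ids)

#' @rdname n_subjects
#' @export
n_snps <- function(x) length(x$snp_ids)

#' Materialize genotype rows
#'
#' Returns the requested subject rows as a dense integer matrix, decoding
#' them from the PLINK backing store when the dataset is lazy. This is the
#' batch accessor the trainer uses, so mini-batch training never needs the
#' full matrix resident at once.
#'
#' @param dataset a \code{genotype_dataset}.
#' @param rows subject indices (default all).
#' @return integer matrix \code{length(rows)} x m.
#' @export
fetch_genotypes <- function(dataset, rows = seq_len(n_subjects(dataset))) {
  if (!is.null(dataset$genotypes)) {
    return(dataset$genotypes[rows, , drop = FALSE])
  }
  plink_decode_rows(dataset$backend, rows)
}

#' Apply a function over subject blocks
#'
#' Streams the cohort in blocks of rows, materializing one block at a time.
#'
#' @param dataset a \code{genotype_dataset}.
#' @param block_size rows per block.
#' @param fun function of (genotype block, row indices).
#' @return list of \code{fun} results, one per block.
#' @export
subject_blocks <- function(dataset, block_size, fun) {
  n <- n_subjects(dataset)
  starts <- seq(1L, n, by = block_size)
  lapply(starts, function(s) {
    rows <- s:min(s + block_size - 1L, n)
    fun(fetch_genotypes(dataset, rows), rows)
  })
}

#' Phenotype matrix container
#'
#' A subjects x traits binary outcome matrix; prevalences are always the
#' column means of the outcomes, recomputed at construction.
#'
#' @param outcomes n x d matrix with entries in \{0, 1\}.
#' @param trait_names d trait labels (taken from column names if missing).
#' @param sample_ids optional subject identifiers; row order must align with
#'   the genotype dataset the phenotypes accompany.
#' @return An object of class \code{"phenotype_matrix"}.
#' @export
phenotype_matrix <- function(outcomes, trait_names = colnames(outcomes),
                             sample_ids = NULL) {
  outcomes <- as.matrix(outcomes)
  if (is.null(trait_names)) {
    trait_names <- paste0("trait", seq_len(ncol(outcomes)))
  }
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary 0/1")
  storage.mode(outcomes) <- "integer"
  if (length(trait_names) != ncol(outcomes)) stop("trait_names length mismatch")
  if (anyDuplicated(trait_names)) stop("trait_names must be unique")
  if (!is.null(sample_ids) && length(sample_ids) != nrow(outcomes)) {
    stop("sample_ids length mismatch")
  }
  prev <- colMeans(outcomes)
  empty <- prev == 0
  if (any(empty)) {
    warning("trait(s) with no cases: ",
            paste(trait_names[empty], collapse = ", "))
  }
  dimnames(outcomes) <- list(NULL, trait_names)
  structure(list(outcomes = outcomes,
                 trait_names = as.character(trait_names),
                 prevalences = unname(prev),
                 sample_ids = if (is.null(sample_ids)) NULL
                              else as.character(sample_ids)),
            class = "phenotype_matrix")
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf("phenotype_matrix: %d subjects x %d traits; prevalence %s\n",
              nrow(x$outcomes), length(x$trait_names),
              paste(sprintf("%s=%.3f", x$trait_names, x$prevalences),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.phenotype_matrix <- function(x) dim(x$outcomes)

#' Read a binary phenotype table
#'
#' Expects a tab-separated file with a header of trait names, one row per
#' subject and 0/1 cells. An optional first column named \code{sample_id}
#' carries subject identifiers; when \code{genotypes} is supplied the ids
#' (or, without ids, the row count) are checked against it.
#'
#' @param path file path.
#' @param genotypes optional \code{genotype_dataset} to align against.
#' @return a [phenotype_matrix()].
#' @export
read_phenotypes <- function(path, genotypes = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  sample_ids <- NULL
  if (ncol(tab) > 0 && names(tab)[1] == "sample_id") {
    sample_ids <- as.character(tab[[1]])
    tab <- tab[, -1, drop = FALSE]
  }
  out <- as.matrix(tab)
  if (!is.numeric(out) || !all(out %in% c(0, 1))) {
    stop("phenotype cells must all be 0 or 1")
  }
  ph <- phenotype_matrix(out, trait_names = colnames(tab),
                         sample_ids = sample_ids)
  if (!is.null(genotypes)) {
    if (nrow(ph$outcomes) != n_subjects(genotypes)) {
      stop("phenotype rows do not match genotype subjects")
    }
    if (!is.null(ph$sample_ids) &&
        !identical(ph$sample_ids, genotypes$sample_ids)) {
      stop("phenotype sample_ids do not align with genotype sample_ids")
    }
  }
  ph
}

#' Write a phenotype matrix as TSV
#' @param phenotypes a \code{phenotype_matrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  df <- as.data.frame(phenotypes$outcomes, check.names = FALSE)
  if (!is.null(phenotypes$sample_ids)) {
    df <- cbind(sample_id = phenotypes$sample_ids, df)
  }
  write_table(df, path)
}

#' Write a rectangular table as TSV
#'
#' Deterministic row order (as given), tab separators, header, no quoting,
#' UTF-8. Numeric values keep 15 significant digits so a write/read round
#' trip preserves them well beyond 12 digits.
#'
#' @param rows a data.frame or matrix; a list of equal-length columns is
#'   accepted, ragged input is an error.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(rows, path) {
  if (is.list(rows) && !is.data.frame(rows)) {
    len <- vapply(rows, length, 1L)
    if (length(unique(len)) > 1) stop("ragged records: column lengths differ")
    rows <- as.data.frame(rows, check.names = FALSE,
                          stringsAsFactors = FALSE)
  }
  if (is.matrix(rows)) rows <- as.data.frame(rows, check.names = FALSE)
  num <- vapply(rows, is.double, TRUE)
  rows[num] <- lapply(rows[num], function(v) {
    ifelse(is.na(v), NA, sprintf("%.15g", v))
  })
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}
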