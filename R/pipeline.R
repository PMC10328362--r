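#' Experiment configuration
#'
#' One object describing a full end-to-end run: simulate (or load) a
#' cohort, train the multi-task model and per-trait single-task baselines,
#' benchmark them, train a decoy-augmented model, interpret it and compute
#' genetic correlations. A global seed fans out to stage-specific seeds via
#' fixed documented offsets, so adding a stage never perturbs earlier
#' stages' randomness.
#'
#' @param sim a [sim_config()] (or NULL with \code{plink_prefix} /
#'   \code{phenotype_file} set to load data from disk).
#' @param plink_prefix,phenotype_file optional input files instead of
#'   simulation.
#' @param hidden,dropout_rate,penalty model settings shared by MTL and STL.
#' @param epochs,batch_size,learning_rate training settings.
#' @param fdr_levels FDR levels for important-SNP selection (default
#'   \code{c(0.001, 0.05)}); correlations use the largest level.
#' @param aggregate importance aggregation, see [model_importance()].
#' @param seed global seed.
#' @return object of class \code{"experiment_config"}.
#' @export
experiment_config <- function(sim = NULL, plink_prefix = NULL,
                              phenotype_file = NULL,
                              hidden = c(64, 32, 16), dropout_rate = 0.5,
                              penalty = 1e-3, epochs = 30, batch_size = 512,
                              learning_rate = 1e-3,
                              fdr_levels = c(0.001, 0.05),
                              aggregate = "abs_mean", seed = 1L) {
  if (is.null(sim) && (is.null(plink_prefix) || is.null(phenotype_file))) {
    stop("either a sim config or plink_prefix + phenotype_file is required")
  }
  if (any(fdr_levels <= 0 | fdr_levels >= 1)) {
    stop("fdr_levels must lie in (0, 1)")
  }
  structure(list(sim = sim, plink_prefix = plink_prefix,
                 phenotype_file = phenotype_file, hidden = hidden,
                 dropout_rate = dropout_rate, penalty = penalty,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, fdr_levels = fdr_levels,
                 aggregate = aggregate, seed = as.integer(seed)),
            class = "experiment_config")
}

# stage seed offsets for the experiment pipeline
stage_seed <- function(config, stage) {
  offs <- c(data = 0L, split = 11L, mtl = 101L, stl = 1009L,
            decoys = 20011L, decoy_model = 30011L)
  (config$seed + offs[[stage]]) %% .Machine$integer.max
}

#' Run a full experiment
#'
#' simulate/load -> split -> train MTL + per-trait STL baselines ->
#' benchmark on the test set -> train a decoy-augmented MTL -> importance,
#' FDR selection at each configured level, overlaps, genetic correlations.
#' Re-running with the same config reproduces every number bit-for-bit on
#' one platform. All tables are written under \code{out_dir} as TSV when it
#' is given; partial outputs are retained if a later stage fails.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory for TSV artifacts.
#' @param verbose print stage progress.
#' @return object of class \code{"lina_report"}: metrics tables for MTL
#'   and STL, the model comparison, per-trait selected SNP counts and
#'   sets, the pairwise overlap matrix, the correlation report and a
#'   provenance block (config, seeds, package version, config hash).
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  emit <- function(tab, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_table(as.data.frame(tab), file.path(out_dir, name))
    }
  }
  stage <- "simulate"
  res <- tryCatch({
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- stage_seed(config, "data")
      cohort <- simulate_cohort(sim)
    } else {
      cohort <- list(genotypes = read_plink(config$plink_prefix),
                     effects = NULL)
      cohort$phenotypes <- read_phenotypes(config$phenotype_file,
                                           cohort$genotypes)
    }
    say("stage simulate: %d x %d, %d traits", n_subjects(cohort$genotypes),
        n_snps(cohort$genotypes), length(cohort$phenotypes$trait_names))

    stage <- "split"
    split <- split_cohort(n_subjects(cohort$genotypes),
                          seed = stage_seed(config, "split"))

    stage <- "train-mtl"
    fit_args <- list(hidden = config$hidden,
                     dropout_rate = config$dropout_rate,
                     epochs = config$epochs, batch_size = config$batch_size,
                     learning_rate = config$learning_rate, split = split)
    mtl <- do.call(lina, c(list(cohort$genotypes, cohort$phenotypes,
                                penalty = config$penalty,
                                seed = stage_seed(config, "mtl")), fit_args))
    say("stage train-mtl: best epoch %d", mtl$best_epoch)

    stage <- "train-stl"
    traits <- cohort$phenotypes$trait_names
    stls <- lapply(seq_along(traits), function(t) {
      do.call(stl_net, c(list(cohort$genotypes, cohort$phenotypes,
                              trait = traits[t],
                              seed = stage_seed(config, "stl") + t),
                         fit_args))
    })
    names(stls) <- traits

    stage <- "benchmark"
    metrics_mtl <- evaluate_metrics(mtl, cohort$genotypes, cohort$phenotypes)
    metrics_stl <- do.call(rbind, lapply(traits, function(t) {
      y <- cohort$phenotypes$outcomes[, t, drop = FALSE]
      evaluate_metrics(stls[[t]], cohort$genotypes, y,
                       subset = split$test)
    }))
    class(metrics_stl) <- class(metrics_mtl)
    comparison <- compare_models(metrics_mtl, metrics_stl)
    emit(metrics_mtl, "metrics_mtl.tsv")
    emit(metrics_stl, "metrics_stl.tsv")
    emit(comparison$per_trait, "comparison.tsv")

    stage <- "decoys"
    decoyed <- make_decoys(cohort$genotypes,
                           seed = stage_seed(config, "decoys"))
    decoy_mtl <- do.call(lina, c(list(decoyed, cohort$phenotypes,
                                      penalty = config$penalty,
                                      seed = stage_seed(config, "decoy_model")),
                                 fit_args))
    say("stage decoys: decoy model best epoch %d", decoy_mtl$best_epoch)

    stage <- "interpret"
    imp <- model_importance(decoy_mtl, decoyed,
                            aggregate = config$aggregate)
    emit(as.data.frame(imp), "importance.tsv")
    selections <- list()
    counts <- data.frame(trait = traits)
    for (lev in config$fdr_levels) {
      sel <- lapply(traits, function(t) {
        crv <- fdr_curve(imp, t)
        suppressWarnings(select_at_fdr(crv, imp, t, lev))
      })
      names(sel) <- traits
      selections[[sprintf("fdr_%g", lev)]] <- sel
      counts[[sprintf("n_at_fdr_%g", lev)]] <-
        vapply(sel, function(s) length(s$snp_ids), 0L)
    }
    emit(counts, "snp_counts.tsv")

    stage <- "correlate"
    top_level <- sprintf("fdr_%g", max(config$fdr_levels))
    sets <- lapply(selections[[top_level]], `[[`, "snp_ids")
    overlaps <- overlap_table(sets)
    correlations <- correlation_report(imp, sets)
    emit(cbind(trait = rownames(overlaps), as.data.frame(overlaps)),
         "overlaps.tsv")
    emit(correlations, "correlations.tsv")

    provenance <- list(config = unclass(config),
                       package_version = as.character(
                         utils::packageVersion("linaprs")),
                       config_hash = config_hash(config),
                       best_epoch_mtl = mtl$best_epoch,
                       best_epoch_decoy_mtl = decoy_mtl$best_epoch,
                       split_seed = split$seed)
    structure(list(metrics_mtl = metrics_mtl, metrics_stl = metrics_stl,
                   comparison = comparison, snp_counts = counts,
                   selections = selections, overlaps = overlaps,
                   correlations = correlations, importance = imp,
                   models = list(mtl = mtl, stl = stls,
                                 decoy_mtl = decoy_mtl),
                   provenance = provenance),
              class = "lina_report")
  }, error = function(e) {
    stop(sprintf("experiment failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(out_dir)) {
    yaml::write_yaml(res$provenance[c("config_hash", "package_version",
                                      "best_epoch_mtl",
                                      "best_epoch_decoy_mtl", "split_seed")],
                     file.path(out_dir, "provenance.yaml"))
  }
  res
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.lina_report <- function(x, ...) {
  cat("LINA experiment report\n")
  cat(sprintf("  mean test ROC AUC: MTL %.4f vs STL %.4f\n",
              mean(x$metrics_mtl$roc_auc, na.rm = TRUE),
              mean(x$metrics_stl$roc_auc, na.rm = TRUE)))
  cat(sprintf("  traits where MTL beats STL on ROC AUC: %d of %d\n",
              x$comparison$n_mtl_wins_roc, nrow(x$comparison$per_trait)))
  cat("  selected-SNP counts:\n")
  print(x$snp_counts, row.names = FALSE)
  invisible(x)
}

#' Compare multi-task and single-task metrics
#'
#' Per-trait relative increases of ROC AUC (baseline 0.5) and PR AUC
#' (baseline = prevalence), winner flags, counts of traits won and column
#' means of the relative increases.
#'
#' @param metrics_mtl,metrics_stl [evaluate_metrics()] records over the
#'   same traits (same order).
#' @return list with \code{per_trait} (data.frame), \code{n_mtl_wins_roc},
#'   \code{n_mtl_wins_pr}, \code{mean_relative_increase_roc},
#'   \code{mean_relative_increase_pr}.
#' @export
compare_models <- function(metrics_mtl, metrics_stl) {
  if (!identical(metrics_mtl$trait, metrics_stl$trait)) {
    stop("metrics records cover different traits")
  }
  safe_ri <- function(model, stl, base) {
    ifelse(stl == base, NA_real_,
           ((model - base) - (stl - base)) / (stl - base) * 100)
  }
  ri_roc <- safe_ri(metrics_mtl$roc_auc, metrics_stl$roc_auc, 0.5)
  ri_pr <- safe_ri(metrics_mtl$pr_auc, metrics_stl$pr_auc,
                   metrics_stl$prevalence)
  if (any(!is.na(metrics_stl$roc_auc) & metrics_stl$roc_auc == 0.5)) {
    warning("single-task ROC AUC at baseline for some trait(s); ",
            "relative increase undefined there")
  }
  per_trait <- data.frame(trait = metrics_mtl$trait,
                          prevalence = metrics_mtl$prevalence,
                          roc_auc_mtl = metrics_mtl$roc_auc,
                          roc_auc_stl = metrics_stl$roc_auc,
                          relative_increase_roc = ri_roc,
                          pr_auc_mtl = metrics_mtl$pr_auc,
                          pr_auc_stl = metrics_stl$pr_auc,
                          relative_increase_pr = ri_pr,
                          mtl_wins_roc = metrics_mtl$roc_auc >
                            metrics_stl$roc_auc,
                          mtl_wins_pr = metrics_mtl$pr_auc >
                            metrics_stl$pr_auc)
  list(per_trait = per_trait,
       n_mtl_wins_roc = sum(per_trait$mtl_wins_roc, na.rm = TRUE),
       n_mtl_wins_pr = sum(per_trait$mtl_wins_pr, na.rm = TRUE),
       mean_relative_increase_roc = mean(ri_roc, na.rm = TRUE),
       mean_relative_increase_pr = mean(ri_pr, na.rm = TRUE))
}

#' Published UK Biobank pan-cancer benchmark table
#'
#' The per-cancer test AUC table from a published UK Biobank benchmark of
#' multi-task versus single-task PRS models (17 cancers with prevalence
#' above 0.5\%): single-task, pan-cancer and pan-disease multi-task ROC and
#' PR AUC (percent), the printed relative-increase columns (integer
#' percent) and prevalences. Used in worked examples and to exercise the
#' relative-increase arithmetic against printed values.
#'
#' @return data.frame, one row per cancer.
#' @export
reported_benchmark <- function() {
  path <- system.file("extdata", "ukb_cancer_benchmark.tsv",
                      package = "linaprs")
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
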