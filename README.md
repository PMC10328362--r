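# linaprs

Parallel estimation of polygenic risk scores (PRS) for many binary disease
traits with a **multi-task linearizing neural network (MTL LINA)**, plus the
machinery needed to evaluate and interpret such models end to end: a
single-task feedforward baseline, exact model-wise interpretation with
decoy-SNP false-discovery-rate control, Spearman genetic correlations
between traits, native PLINK1 genotype I/O, and a liability-threshold
cohort simulator with tunable pleiotropy.

## Who this is for

Statistical geneticists and ML-for-genomics researchers who want to study
*whether jointly learning many traits improves PRS accuracy* (positive
transfer through shared genetic basis), and to identify which SNPs a
trained multi-task model actually uses per trait, with an empirical FDR on
that selection — without needing access to a biobank to develop and test
the machinery.

## The model

For a genotype vector $X \in \{0,1,2\}^m$ (0 = homozygous minor allele,
1 = heterozygous, 2 = homozygous major) the network predicts all $d$ traits
at once:

$$Y = S\big(K\,(A \circ X) + B\big), \qquad A = F(X)$$

where $S$ is the element-wise sigmoid, $K$ is a $d \times m$ coefficient
matrix, $B$ a bias vector, and $A$ an attention vector produced from $X$ by
a shared three-hidden-layer subnetwork $F$ (leaky-ReLU, dropout,
batch-norm; linear attention layer). Training minimizes
$W^\top E + \beta\lVert K\rVert_2$ (per-trait cross-entropies $E$, trait
weights $W$, Frobenius penalty on $K$) with mini-batch Adam, a 70/15/15
subject split, per-epoch checkpointing and best-on-validation selection.

Because the model is **exactly linear in $X$ given $A$**, the coefficient
of SNP $j$ for trait $t$ at input $x$ is $K_{tj}A_j(x)$ with no
approximation; per-SNP importance scores, per-pair interaction scores
(from the attention Jacobian), and decoy-calibrated FDR thresholds all
build on that identity. See the methods vignette
(`vignettes/mtl-lina-prs.Rmd`) for the full account.

## Worked example

Simulate a pleiotropic cohort, fit the multi-task model and a single-task
baseline, compare them, and interpret the multi-task model with decoy FDR
control:

```r
library(linaprs)

cfg <- sim_config(n_subjects = 4000, n_snps = 300, n_traits = 4,
                  n_causal_per_trait = 20, shared_fraction = 0.8,
                  heritability = 0.6, prevalences = 0.1, seed = 11)
cohort <- simulate_cohort(cfg)
split  <- split_cohort(4000, seed = 12)

fit <- lina(cohort$genotypes, cohort$phenotypes, hidden = c(64, 32, 16),
            epochs = 100, learning_rate = 1e-2, split = split, seed = 13)
fit
#> Multi-task LINA model
#>   300 SNPs -> 64/32/16 -> attention(300) ; 4 traits
#>   best epoch 40/100 (validation metric 0.8467)
#>   traits: trait01, trait02, trait03, trait04

evaluate_metrics(fit, cohort$genotypes, cohort$phenotypes)
#>     trait   n n_case prevalence   roc_auc    pr_auc
#> 1 trait01 600     73 0.12166667 0.7882821 0.3822055
#> 2 trait02 600     58 0.09666667 0.8659817 0.4724327
#> 3 trait03 600     60 0.10000000 0.7768210 0.3321785
#> 4 trait04 600     62 0.10333333 0.8117580 0.3920452
```

Held-out metrics are computed on the model's test split automatically.
Per-trait ROC AUCs of 0.78–0.87 against a 0.5 baseline, and PR AUCs of
0.33–0.47 against prevalence baselines of ~0.1: the model has learned
genuine polygenic signal. Now the decoy-calibrated interpretation:

```r
decoyed <- make_decoys(cohort$genotypes, seed = 14)
dfit <- lina(decoyed, cohort$phenotypes, hidden = c(64, 32, 16),
             epochs = 60, learning_rate = 3e-3, split = split, seed = 15)
imp <- model_importance(dfit, decoyed)   # test-set subjects, eval mode
crv <- fdr_curve(imp, "trait01")
sel <- select_at_fdr(crv, imp, "trait01", target_fdr = 0.05)
str(sel[c("threshold", "fdr_estimate", "n_real", "n_decoy")])
#> List of 4
#>  $ threshold   : num 0.0899
#>  $ fdr_estimate: num 0
#>  $ n_real      : int 9
#>  $ n_decoy     : int 0
sum(sel$snp_ids %in% cohort$genotypes$snp_ids[cohort$effects$causal_mask[1, ]])
#> [1] 8
```

At a nominal 5% FDR, 9 real SNPs are selected with no decoy above the
threshold (estimated FDR 0), and 8 of the 9 are genuinely among the 20
planted causal SNPs for the trait — the decoy calibration is doing its
job on the strong end of the signal. Genetic correlations between traits over the union of their selected
sets come from `genetic_correlation()` / `correlation_report()`, and
`run_experiment()` chains the whole pipeline (simulate → train MTL + STL →
benchmark → decoy interpretation → correlations) behind one config, with
every table written as TSV.

A command-line front end with the same stages is installed at
`inst/scripts/lina-cli.R` (`simulate`, `train`, `evaluate`, `interpret`,
`correlate`, `run`).

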