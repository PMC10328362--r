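---
title: "Multi-task linearizing networks for polygenic risk scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task linearizing networks for polygenic risk scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`linaprs` estimates polygenic risk scores (PRS) for many binary disease
traits *in parallel* with a multi-task linearizing neural network
(MTL LINA). For a subject with genotype vector $X \in \{0,1,2\}^m$
(0 = homozygous minor allele, 1 = heterozygous, 2 = homozygous major
allele) the model predicts the $d$-vector of trait probabilities

$$Y = S\big(K\,(A \circ X) + B\big), \qquad A = F(X),$$

where $S$ is the element-wise sigmoid, $K$ a $d \times m$ coefficient
matrix, $B$ a $d$-vector of biases, $\circ$ the element-wise product and
$A$ an $m$-unit *attention vector* produced by a feedforward subnetwork
$F$ with three hidden layers (leaky-ReLU, dropout, batch normalization)
and a linear output layer. All traits share $F$ (hard parameter sharing up
to the attention layer); each trait owns one row of $K$ and one bias.

The defining property is *linearization*: conditional on $A$, the model is
exactly a per-trait logistic regression in $X$ with coefficients
$K_{tj} A_j(x)$. Nothing about the interpretation below is approximate or
sampled — it reads coefficients off this identity.

The training loss is

$$\mathrm{loss} = W^{\mathsf T} E + \beta \lVert K \rVert_2,$$

with $E$ the vector of per-trait mean binary cross-entropies over the
batch, $W$ nonnegative trait weights (all 1 by default: no re-weighting
for class imbalance; the simulator's prevalence control is the realism
knob) and $\lVert K\rVert_2$ the Frobenius norm of $K$. The norm is
penalized *literally*, not squared; a squared variant is available via
`squared_penalty = TRUE` for comparison. At $K = 0$ the norm is not
differentiable and the implementation uses the zero subgradient.

The single-task baseline (`stl_net()`) is a plain feedforward net with the
same three hidden-layer sizes and a single sigmoid output, trained with
binary cross-entropy under the identical split/optimizer/selection
protocol, so MTL-vs-STL comparisons isolate the effect of joint learning.

### Architecture choices that the defining equations leave open

* **Block ordering.** Inside each hidden block the order is affine →
  batch-norm → leaky-ReLU → dropout. Interpretation only relies on
  eval-mode behaviour, which is piecewise affine for any of the standard
  orderings.
* **Leaky-ReLU slope** defaults to 0.01 (`leaky_slope`).
* **Readout.** The defining equation has a single affine readout per trait
  (a row of $K$). A description of the architecture as having a "task
  specific hidden layer" per trait would add capacity between the shared
  representation and each output; we implement the equation as written,
  since it is the form for which the linearization identity — the point of
  the architecture — holds exactly.
* **Initialization** (unstated by the defining equations): Kaiming-uniform
  weights, zero biases, unit batch-norm scale. Acceptance of the model is
  property-based, so any standard scheme works; the chosen one is seeded
  and bit-reproducible.

## Training protocol

The cohort is split at the subject level into 70% training, 15%
validation and 15% test (`split_cohort()`). Training uses mini-batches of
512 with Adam at initial learning rate $10^{-4}$ for 100 epochs, with one
checkpoint per epoch; the checkpoint with the best validation performance
(default: mean validation ROC AUC over traits, `selection = "loss"`
available) is the fitted model, ties to the earliest epoch. All of these
are package defaults mirroring the protocol the architecture was designed
under, and all are configurable.

**Desk-scale adjustment.** The defaults target biobank-scale cohorts
(hundreds of optimizer steps per epoch). A cohort of a few thousand
subjects yields only ~6 steps per epoch, so the package's own tests and
the acceptance script use a proportionally larger learning rate
($10^{-3}$–$10^{-2}$) and 60–100 epochs, with hidden sizes 64/32/16
instead of 1000/250/50. These are small-data choices made once, on
optimizer-arithmetic grounds (comparable total step × rate budget), and
are used identically for MTL and STL so comparisons stay fair. The
problem sizes exercised are $n = 4000$, $m = 300$ real SNPs (+300 decoys
where decoys are needed), $d \le 8$ traits.

Batch normalization uses biased batch variance in training mode and
running statistics accumulated with momentum 0.1 ($\varepsilon = 10^{-5}$)
in eval mode; dropout is inverted (scaled at train time). Training-mode
losses are therefore stochastic; everything reported by the package
(validation metrics, predictions, interpretation) is computed in eval
mode, which is deterministic and piecewise linear. Non-finite training
loss aborts with a diagnostic rather than continuing silently.

Gradients are hand-derived reverse-mode and verified in the test suite
against central finite differences across every parameter tensor,
including the batch-norm path.

## Interpretation

**First order.** By the linearization identity the instance-wise
coefficient of SNP $j$ for trait $t$ at input $x$ is $c_{tj}(x) =
K_{tj} A_j(x)$, exactly. The model-wise importance score aggregates over
an interpretation cohort — the test split, in eval mode:

$$s_{tj} = \big|\operatorname{mean}_x K_{tj} A_j(x)\big|
         = \big|K_{tj}\big| \cdot \big|\operatorname{mean}_x A_j(x)\big|.$$

The signed-mean-then-absolute default keeps $s_{tj}$ interpretable as the
magnitude of a coherent model-wise linear coefficient; the alternative
$\operatorname{mean}_x |c_{tj}(x)|$ is available
(`aggregate = "mean_abs"`) and the choice is recorded in the output.
Only SNPs on non-sex chromosomes are retained (labels X, Y, XY, MT and
23–26 are dropped at interpretation time, not at load time).

**Second order.** For the pre-sigmoid output
$z_i = \sum_j K_{ij} A_j(x) x_j + B_i$, the Hessian is

$$H^{(i)}_{kl} = K_{ik} J_{kl} + K_{il} J_{lk}, \qquad
  J_{jk} = \partial A_j / \partial x_k,$$

exact away from activation kinks because the eval-mode attention map is
piecewise linear (its own second derivative vanishes), so the Hessian of
the output reduces to the Jacobian of the attention vector. $J$ is
computed in closed form as a product of layer weight matrices, batch-norm
scales and local activation slopes; tests confirm agreement with central
finite differences, which are exact here up to rounding because $z_i$ is
locally quadratic.

**Decoy-based FDR.** To calibrate importance thresholds without ground
truth, a *decoy* copy of every real SNP is appended to the input
(`make_decoys()`): decoy $j$ is sampled i.i.d. per subject from real SNP
$j$'s *empirical* genotype distribution, so it matches the real SNP's
homozygous-minor/heterozygous/homozygous-major frequencies but is
independent of every trait by construction. A fresh model is trained on
the decoy-augmented input (decoys are never bolted onto an already-trained
model, whose scores they could not influence), and for any importance
threshold the estimated FDR is

$$\widehat{\mathrm{FDR}}(s) =
  \frac{\#\{\text{decoys} \ge s\}}{\#\{\text{reals} \ge s\}}.$$

Thresholds are inclusive and ties enter together. No pseudocount is added
by default, so a threshold above every decoy has estimated FDR 0
(a `pseudocount = TRUE` option adds +1 to the decoy count for conservative
use). `select_at_fdr()` returns the real SNPs at or above the *smallest*
threshold whose estimate is within the target — the maximal qualifying
selection, the same convention as q-value/knockoff-style procedures. The
estimate is empirical: it carries no exchangeability guarantee, and the
synthetic-cohort tests accept mean empirical FDP up to twice the nominal
level.

**Genetic correlation.** For two traits the package reports the Spearman
rank correlation (mid-rank ties) between their importance scores over the
union of their FDR-selected SNP sets (5% by default), plus union and
intersection sizes and pairwise/3-way overlap counts.

## The cohort simulator

No biobank data ship with the package; `sim_config()` +
`simulate_cohort()` generate cohorts with exactly the structure the
method assumes:

* **Genotypes.** Independent biallelic SNPs in Hardy–Weinberg proportions
  $p^2 : 2p(1-p) : (1-p)^2$ with minor-allele frequencies drawn uniformly
  from `maf_range` (default 0.05–0.5); SNPs are assigned round-robin to
  autosomes 1–22. There is deliberately no linkage disequilibrium: none of
  the package's operations require LD, and independent SNPs make the
  planted-causal ground truth unambiguous for calibration tests.
* **Effects and pleiotropy.** A pleiotropic pool of
  $\mathrm{round}(\texttt{shared\_fraction} \times k)$ SNPs is drawn once;
  every trait uses the whole pool and fills up to its $k$ causal SNPs
  privately. Expected pairwise causal overlap is therefore
  $\approx \texttt{shared\_fraction} \times k$. Nonzero effects are drawn
  Normal and then rescaled so each trait's genetic variance on
  standardized genotypes is *exactly* the heritability $h^2$ — without the
  rescaling, the chi-square spread of the summed squared effects lets
  realized prevalences drift several binomial standard errors off target.
* **Phenotypes.** Liability threshold model, the standard generative model
  for binary polygenic traits: $L_t = \sum_j \beta_{tj} z_j +
  \varepsilon$, $\varepsilon \sim N(0, 1 - h^2)$, case iff $L_t$ exceeds
  the standard-normal quantile of $1 - \mathrm{prevalence}_t$. Default
  prevalences (5–10%) sit at the upper end of the rare-trait regime the
  method targets; tests use 5–20% so that test splits retain enough cases
  for defined metrics.
* **Decoys** use empirical (not generative) genotype proportions, matching
  the construction above.

Everything is bit-reproducible given `seed`; stage seeds are derived by
fixed documented offsets so adding a stage never changes earlier stages'
randomness.

**What passing tests on these cohorts does and does not show.** The
simulator reproduces the *statistical skeleton* the method assumes: HWE
genotypes, sparse additive liabilities, shared causal SNPs, rare binary
outcomes, frequency-matched null decoys. It omits LD, population
structure, relatedness, genotyping error and sex-linked effects. Positive
transfer or FDR calibration on these cohorts demonstrates that the
implementation behaves as designed under its own assumptions — not that
the same gains materialize on any particular real cohort.

## Evaluation metrics

ROC AUC uses the rank (Mann–Whitney) statistic with mid-rank ties —
identical to the trapezoidal area under the empirical ROC curve, and
exactly 0.5 when all scores tie. PR AUC uses step-wise average precision
(ties grouped), the conservative standard for imbalanced data;
trapezoidal PR interpolation is deliberately not used. The ROC baseline
is 0.5; the PR baseline is the prevalence. Traits with a single class in
the evaluation set are reported as `NA` with a warning, never as a silent
zero. The transfer statistic is the relative increase of over-baseline
AUC gain,

$$\frac{(\mathrm{AUC}_{\mathrm{MTL}} - b) - (\mathrm{AUC}_{\mathrm{STL}} - b)}
       {\mathrm{AUC}_{\mathrm{STL}} - b} \times 100\%,$$

which is undefined (an error) when the single-task AUC sits exactly at
the baseline — near that point the statistic explodes, which is why
per-trait values in published comparisons can reach four digits.

## File formats and degenerate inputs

PLINK1 .bed/.bim/.fam is read and written natively (SNP-major, magic
bytes `6C 1B 01`), with the .bim A1 allele taken as the minor allele so
PLINK's codes map directly onto the 0/1/2 minor-homozygote convention.
Missing genotype calls (code `01`) are imputed to the SNP's modal
genotype by default; `missing = "strict"` refuses them. Lazy reading
decodes subject blocks on demand, so training streams batches without
ever materializing the full decoded matrix. Checkpoints are JSON
containers (schema `linaprs-checkpoint` v1) holding the config, all
weights and batch-norm statistics; interpretation can restart from a
checkpoint without retraining. Tables are TSV with 15 significant digits.

## Known limitations

* Pure-R training: perfectly adequate at the desk scales above (a 100-epoch
  fit at $n = 4000$, $m = 600$ takes ~20 s on one core) but not intended
  for hundreds of thousands of SNPs.
* No covariate adjustment (age, sex, principal components) — absent from
  the defining model equations; residualize upstream if needed.
* The decoy FDR estimate is empirical, with no finite-sample
  exchangeability guarantee.
* `simulate_phenotypes` standardizes genotypes empirically; monomorphic
  columns contribute zero liability.
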