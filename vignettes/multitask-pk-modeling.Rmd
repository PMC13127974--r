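---
title: "Multi-task gradient boosting for clearance and volume of distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task gradient boosting for clearance and volume of distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modeling problem

Human clearance (CL, mL/min/kg) and steady-state volume of distribution
(VDss, L/kg) are the two pharmacokinetic parameters that jointly determine
a drug's exposure and half-life. They are physiologically coupled — both
reflect tissue binding, lipophilicity and plasma protein binding — yet
most structure-based prediction models treat them as independent
regression targets. `pkboost` implements a multi-task gradient boosting
machine (MTGBM) in which every regression tree has **one shared
structure** (the same splits route every compound) but **one leaf value
per task**, so that split selection pools evidence from both endpoints
while leaf predictions stay task-specific.

## The boosting engine

Each task t uses the squared-error objective on the transformed target
scale, so for prediction p and target y the gradient is `g_t = p_t - y_t`
and the Hessian is `h_t = 1` wherever the target is observed; a compound
missing one target contributes `g = h = 0` to that task and still informs
the shared structure through the other task. A candidate split with
left/right gradient sums `G_L, G_R` and Hessian sums `H_L, H_R` scores

    gain = sum_t [ G_Lt^2 / (H_Lt + lambda2)
                 + G_Rt^2 / (H_Rt + lambda2)
                 - G_t^2  / (H_t  + lambda2) ]

i.e. the standard second-order gain summed over tasks. The engine scans
all features and all midpoint thresholds of sorted unique values exactly
(no histogram binning: the package targets cohorts of at most a few
thousand compounds, and exact scans make the engine directly comparable
to a brute-force oracle in the tests). Trees grow best-first (leaf-wise)
up to `num_leaves` under a `max_depth` cap, and each leaf's value per
task is the L1-soft-thresholded Newton step
`w_t = -soft(G_t, lambda1) / (H_t + lambda2)`.

Ties in the split scan break to the lowest feature index, then the lowest
threshold; ties in leaf selection break to the earliest-created node.
These rules make the engine bit-reproducible, which the test suite
exploits: with one task and `lambda1 = 0` the engine must match an
independently coded reference implementation round for round to 1e-9, and
duplicating one target as two tasks must reproduce the single-task fit to
1e-12 (the summed gain doubles, so the argmax split is unchanged).

Default multi-task settings are `learning_rate = 0.014`,
`num_leaves = 44`, `max_depth = 13`, `lambda_l1 = 0.71`,
`lambda_l2 = 2.89`, up to 15,000 rounds with early stopping after 150
rounds without improvement of the *summed-across-tasks* validation MSE
(equal task weights; nothing in the data motivates unequal ones). The
single-task baseline is the same engine with `n_tasks = 1` — a clean
ablation in which the only difference between the compared models is the
shared structure — optionally tuned by random search over learning rate
0.005–0.05 (log scale), 8–64 leaves, depth 6–15, `min_child_samples`
10–50 and L1/L2 in 0.01–10 (log scale), selected by validation GMFE on
the original scale.

## Data model and preprocessing

Input is one row per compound: SMILES, human CL and VDss (either may be
missing, never both), rat/dog/monkey CL and VDss, fraction unbound in
plasma (fup) per species, and acidic/basic pKa. CL and VD tables are
merged on (name, SMILES) after deleting *all* whitespace from both keys —
the most robust reading of cosmetic-whitespace mismatches between source
tables; duplicate keys within one table are an error rather than a silent
collapse.

Quality control removes compounds with human VDss >= 5 L/kg or CL >= 20
mL/min/kg (inclusive thresholds; beyond these limits values are treated
as biologically implausible). Numeric *features* are then winsorized at
the 1st/99th percentiles (type-7 quantiles, i.e. linear interpolation
between order statistics) on the pooled pre-split table; the two human
targets are deliberately not winsorized — their QC is the physiological
filter, and pooling target values across partitions would let held-out
targets influence the fitted scalers. Targets and animal PK columns get
`log1p` + standardization (these spans 2–3 decades and are right-skewed;
`log1p` also tolerates values near zero), fup and pKa are standardized
only, and columns prefixed `Caco_2` or `water_solubility` are passed
through untouched. All scaler parameters are fit **on the training
partition only** and stored for exact inversion (round-trip error below
1e-10 is a tested contract).

The 60/20/20 split can be chosen from 10,000 random candidates by a
distribution-similarity criterion: the mean over the two targets (log1p
scale) of the mean pairwise two-sample Kolmogorov–Smirnov statistic among
the three partitions. KS was chosen because it is distribution-free,
cheap, and sensitive to both location and shape differences; the
criterion function is a single place in the code and easy to swap. The
repeated-split protocol (`run_repeated`) instead uses plain seeded random
partitions — stability claims should not depend on a partition optimizer.

## Supervised molecular embeddings

Two per-compound, per-target 2-dimensional embeddings summarize molecular
structure:

* **Descriptor MLP.** A 561-length vector — molecular weight, logP
  estimate, H-bond donor/acceptor counts and TPSA (computed by OpenBabel
  through ChemmineR), a 256-bit radius-2 circular fingerprint, and a
  300-dimensional hashed count vector of radius-0/1 circular substructure
  identifiers — feeds a small multilayer perceptron (1–3 hidden ReLU
  layers of 32–256 units, dropout 0–0.5) ending in a linear
  2-unit bottleneck followed by the regression output. The circular
  fingerprint and the hashed substructure block are computed by the
  package itself with a deterministic integer hash, so the whole vector is
  reproducible without any external model file.
* **Image CNN.** Molecules are rendered deterministically to 224x224x3
  images (bond segments plus colour-coded heteroatom markers drawn from
  OpenBabel 2-D coordinates), average-pooled to a small grid (factor 8 by
  default, 16 in the test profile), and passed through a compact
  convolutional network (3x3 convolutions + ReLU + 2x2 average pooling
  per block, global average pooling, linear 2-unit bottleneck, regression
  output). Weights are randomly initialized; the networks are trained
  from scratch per split.

Both embedders follow a strict three-step protocol per target: (1)
random-search hyperparameter optimization, each trial trained on the
training rows with early stopping and scored on validation loss; (2)
final training on train+validation with the chosen configuration, early
stopping still monitored on the validation rows (the protocol needs *a*
held-back monitor and the test partition is untouchable; this is the one
place where the monitor overlaps the fitting data, and it only selects a
stopping epoch, not parameters); (3) embedding extraction in inference
mode for all rows, with no parameter updates. Training, batching and
dropout are all seeded, so the full protocol is reproducible, and the
tests verify that corrupting targets outside train/validation changes
nothing. The loss is MSE on the transformed target.

## Shadow-feature selection

Per target, candidate features (animal PK, fup, pKa, plus the four
embedding pairs) pass through Boruta-style selection: in each iteration a
row subsample is drawn, every column gets a freshly permuted `shadow_`
copy, a gradient-boosted learner (depth cap 5) is refit, and each real
feature scores a *hit* when its Shapley importance (mean |attribution|
from the package's estimator — exact enumeration up to 10 columns,
kernel sampling above) exceeds the 80th percentile of that iteration's
shadow importances. After `n_iterations` (default 5,000; 100–200 in test
profiles) a two-sided binomial test on the hit count (null probability
0.5, alpha 0.05 Bonferroni-divided by the number of candidates, as in the
reference Boruta implementations) labels the feature accepted, rejected
or tentative; only accepted features survive, and the multi-task model
uses the union of the two accepted lists, CL order first.

Two design choices deserve emphasis because they are what make the
binomial calibration meaningful with a deterministic engine:

* **Row subsampling (1/3 per iteration, without replacement).** With the
  full fixed table, refitting produces the *same* model every iteration,
  so hit indicators are perfectly correlated and the binomial test's
  independence assumption collapses; any column whose chance association
  happens to beat the shadow threshold once beats it always. Boruta's
  original calibration leans on the model variance of random forests;
  subsampling restores that variance and simultaneously dilutes chance
  associations that a single fixed sample always contains.
* **A deliberately compact learner (3 leaves, 10 rounds, lambda2 = 5).**
  Shadow comparison needs a *ranking* of features against their permuted
  copies, not a well-fit model; a high-capacity learner chases chance
  structure in secondary splits and hands real importance to noise
  columns.

A fundamental caveat documented here rather than hidden: with a single
fixed dataset, a "noise" column whose sample correlation with the target
is genuinely large by chance is statistically indistinguishable from a
weakly informative feature, and no within-dataset selector can reject it
with certainty. The calibration above keeps the acceptance probability of
such columns low (measured in the test suite on seeded null data), not
zero by construction.

## Evaluation and comparison

* `mse_log` — MSE of log1p-transformed original-scale values.
* `gmfe` — `10^mean(|log10(pred/obs)|)`, base 10 by pharmacokinetic
  convention; symmetric, scale-invariant, minimum 1. Nonpositive
  predictions are clipped to 1e-6 with a warning rather than crashing an
  evaluation run.
* `r_squared` — computed on the log1p scale so the MSE/R² pair describes
  the same residuals (the alternative, original-scale R², would be
  dominated by the few largest compounds).
* `dm_test` — Diebold–Mariano with squared-error loss differential and
  horizon 1, so the long-run variance is just the lag-0 variance; the
  statistic is referred to the standard normal, two-tailed, with no
  small-sample correction. Zero-variance differentials are flagged
  degenerate (p = 1 when the differential is identically zero, NA
  otherwise) instead of producing infinite statistics.
* `stratified_gmfe` — VDss bins low < 0.5, mid 0.5–2.0 (closed on both
  ends so every compound lands in exactly one bin), high > 2.0 L/kg.
* `summarize_repeats` — per-target mean ± sd (ddof = 1) over repeated
  splits, win counts (strict inequality), and mean deltas separately over
  wins and losses.

## Shapley attribution

Attribution uses the interventional (background-replacement) value
function: v(S) is the mean model output over background rows with the
features in S pinned to the explained compound's values. Exact
enumeration over all 2^M coalitions is available for M <= 12 and serves
as the oracle; above that, a constrained weighted least squares over
coalitions drawn by Shapley-kernel weight (the kernel estimator) is used,
with the sum constraint enforcing local accuracy (base + sum of
attributions = prediction, tested to 1e-6). When the budget covers all
proper coalitions the estimator reproduces the exact values. Defaults
mirror the reduced-cost convention for kernel explanation of the
multi-task model: up to 200 explained test compounds against a 30-row
training background. Tree-path-specific fast attribution is deliberately
not implemented; both model families are explained by the same estimator,
which keeps comparisons between models on one convention. Modality shares
are computed over the top-10 features by mean |attribution|.

## The synthetic cohort generator

Because the study dataset is external, the package ships a generator that
reproduces the *statistical shape* the method assumes: log10 CL and log10
VDss are linear in latent variables `t = sqrt(rho) s + sqrt(1-rho) z +
delta z_mol` sharing a standard-normal factor s (so their log-scale
correlation is exactly `rho_shared` when `delta = 0`); animal log10
values are affine in the matching task latent plus species noise
(allometric structure); fup is a logistic transform of the VD latent
(distribution volume and plasma binding are physiologically linked); pKa
values come from truncated normals; and a configurable fraction of
compounds lose one target (never both). Molecules are random
valence-respecting trees over {C, N, O, S, F, Cl} with optional carbocycle
substituents, written as SMILES by the package and parseable by OpenBabel;
heavy-atom count is the molecular signal that `z_mol` injects into both
targets.

Defaults: `rho_shared = 0.6` (the endpoints are correlated but not
interchangeable; there is no published value to anchor to, so this is a
free parameter), `mu_logCL = 0.6, sigma_logCL = 0.45`,
`mu_logVD = -0.15, sigma_logVD = 0.5` — chosen so that just under 10% of
compounds violate the physiological filter, exercising the QC path
without gutting the cohort — `animal_noise_sd = 0.3`,
`mol_signal_weight = 0.25`, 10% missingness per target. The generator
emulates correlation structure, skew, allometry and missingness; it does
**not** emulate medicinal-chemistry diversity, assay noise structure,
activity cliffs, or any real structure-activity landscape, so passing
tests demonstrate that the pipeline recovers the structure it assumes,
not that it predicts real human PK. True latents are kept in a side
table for diagnostics and never enter any model-fitting path.

## Leakage control

The pipeline blanks test-partition targets before any fitting stage and
routes every target read through an access guard that records the stage
and whether test rows were touched (a non-evaluation stage touching them
is an error). The repeated-split and test profiles use seed-determined
random partitions, under which corrupting test-partition targets provably
changes no fitted artifact — the test suite checks byte-identical hashes
of the split, embedding, selection and model artifacts. With the
optimized split this guarantee cannot hold by construction, because the
partition optimizer compares target distributions across candidate
partitions before any partition exists; that is a property of the
protocol being reproduced, not a fitting-stage leak, and it is why the
stability analysis uses plain random splits.

## Problem sizes and runtime choices

The package's own experiments are sized for a single CPU: the stability
experiment uses a 700-compound cohort with `rho_shared = 0.8`, 10 random
60/20/20 splits, descriptor-MLP embeddings (single-trial budget), no
selection stage, and 400-round boosting schedules; the single-split
pipeline demonstration uses 200 compounds with both embedders in reduced
form (16x average pooling, 4+8 channels, 8 epochs), 200 selection
iterations and 200-round schedules. The full-scale profile
(`pipeline_config("paper")`) keeps the complete budgets (10,000 split
candidates, 100 trials, 5,000 iterations, 15,000 rounds) and is the
configuration a user with hours rather than minutes should run.

## Known limitations

* The CNN is a compact network trained from scratch; with hundreds rather
  than millions of images it mostly captures gross size/branching cues,
  and no pretrained backbone is bundled.
* The 300-d substructure block is a hashed count vector, not a learned
  distributional embedding; it preserves dimensionality and determinism,
  not semantic similarity between substructures.
* Kernel Shapley values for the single-task baseline and the multi-task
  model share one convention, but kernel estimates at sampled budgets
  carry Monte-Carlo error; exact enumeration is only feasible to 12
  features.
* The selection stage's null calibration is statistical, not absolute
  (see above).
* The DM test uses the normal reference; with very small test partitions
  its size is approximate.
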