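---
title: "Binary Political Optimizer for wrapper gene selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary Political Optimizer for wrapper gene selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microarray and RNA-seq experiments measure thousands of genes on a few dozen
samples. For a classifier, most of those genes are noise: selecting a small,
informative subset improves accuracy, interpretability and runtime. With
`nf` genes there are `2^nf − 1` candidate subsets, so exhaustive search is
hopeless and the problem is tackled with stochastic search. `bpofs`
implements a *wrapper* selector: candidate subsets are scored by the
cross-validated accuracy of an actual classifier (KNN), not by per-gene
statistics, so interactions between genes are taken into account at the cost
of many classifier evaluations.

## The optimizer

The search engine is the Political Optimizer, a population metaheuristic
whose operators mimic a multi-party election cycle. A population of
`p × m` candidate solutions is organized two ways at once: `p` *parties* of
`m` members, and `m` *constituencies* each containing the j-th member of
every party. Each solution therefore has two reference solutions — its
party's best member (the *leader*) and its constituency's best candidate
(the *winner*) — and the phases iterate:

1. **Election campaign.** Every member moves coordinate-wise, once toward
   its leader and once toward its winner, using the *recent past-based
   position updating strategy*: a three-case piecewise rule on the ordering
   of the previous coordinate, the current coordinate and the reference
   coordinate. Two case tables exist; the first is used when the member's
   fitness improved (or held) since the last iteration, the second when it
   worsened. Cases are tested in order and the first match wins, which
   resolves every boundary tie deterministically.
2. **Party switching.** Each member is selected with probability
   `λ_t = λ_max (1 − t/T_max)` and swapped with the least-fit member of a
   uniformly chosen other party. The linear decay moves the population from
   exploration to exploitation; the member count and party sizes are
   invariant.
3. **Election.** Leaders, winners and the global-best archive are
   recomputed from current fitnesses; all ties break to the lowest index.
4. **Parliamentary affairs.** Each winner forms a trial position relative
   to another randomly chosen winner and accepts it only on strict
   improvement, so this phase never loses fitness. The update rule is the
   one from the original continuous Political Optimizer, which this
   algorithm builds on; the published binary variant defers the phase
   details to that source.

The engine maximizes; positions initialize uniformly on `[−1, 1]` and every
update is clipped to `[−6, 6]`. The clip bound mirrors the velocity bound
used by comparable binary swarm methods and keeps the transfer functions
(below) away from total saturation, where search would stall.

## Binarization

Feature selection needs bit vectors, while the engine moves continuous
positions. The bridge is a *transfer function* mapping each coordinate to a
probability, followed by a per-coordinate uniform draw: bit = 1 if
`TF(x) ≥ rand`. Two families give the package its two variants:

* **BPO-S** uses the sigmoid `1/(1 + e^−x)` — monotone, 0.5 at the origin,
  so an uninformative coordinate selects its gene half the time.
* **BPO-V** uses `|tanh(x)|` — even, zero at the origin, so coordinates
  near zero drop their gene almost surely. This is why BPO-V tends to
  produce sparser masks and converge faster on gene-expression data.

The hyperbolic tangent itself is negative for negative input and so is not
a probability; the absolute value restores the standard non-negative
V shape. The continuous position remains the search state: binarization
happens at evaluation time only, and the evaluated mask is cached with the
fitness.

## The objective

A mask is scored by

```
F = Acc + ω (1 − sf / nf)
```

where `Acc` is the mean stratified k-fold cross-validated accuracy of a
Euclidean KNN classifier restricted to the selected genes, `sf` the number
of selected genes and `nf` the total. `F` lies in `[0, 1 + ω]`; with the
default `ω = 0.5` the ceiling is 1.5, approached by perfectly accurate
single-gene subsets. Defaults: `ω = 0.5` (the published setting), 10 folds
(the published protocol), `k = 5` neighbours (the neighbour count is not
published; 5 is a common wrapper default and is exposed as a parameter).
Choices the protocol leaves open, resolved here:

* **Scaling.** Genes are min–max scaled with statistics fit on training
  folds only, preventing scale-dominant genes and test leakage. Per-column
  scaling commutes with column selection, which lets the implementation
  prescale each fold once and reduce every mask evaluation to column
  subsetting plus the KNN vote.
* **Stratified folds** (via `caret::createFolds`), because expression
  datasets are small and class-imbalanced; unstratified 10-fold splits can
  produce folds missing a class entirely. Classes rarer than the fold count
  shrink the fold count to the smallest class size, with a warning.
* **Empty masks** are repaired by setting one random bit rather than scored
  zero, keeping the objective defined and the search space connected.
* **Determinism.** Fold assignment and classifier tie-breaking run under a
  seed held in the fitness configuration, so a (data, mask, config) triple
  always scores identically and fitness caching is sound; the optimizer's
  own random stream is unaffected.

## Synthetic data and the oracle

Real benchmark matrices are external downloads, so testing rests on a
generator with known ground truth: `n` samples over `d` genes, balanced
labels, a planted set of informative genes whose class-conditional means
sit `effect_size × noise_sd` apart (the class-to-mean assignment permuted
per gene so planted genes are not mutually redundant), optional redundant
genes (planted genes plus fresh noise), and pure Gaussian noise elsewhere.
The model is deliberately idealized: it has no batch effects, heavy tails,
gene-gene correlation structure or count-data skew, so passing recovery
tests demonstrates correct optimizer behaviour, not performance claims on
real microarrays.

For up to 15 genes, `exhaustive_best()` scores every nonempty mask under
one fixed fold assignment and returns the argmax (ties to the
lexicographically smallest mask). Because the heuristic sees the same
mask-to-fitness map under the same configuration, the oracle value is a
true upper bound for any heuristic run — the basis of the attainment tests.

## Statistics and reporting

Repeated runs (run `i` is seeded `base_seed + i − 1`) are summarized as
best / average / worst / sample standard deviation of the per-run best
fitness, the mean selected-gene count and its percentage, and the mean
recomputed accuracy of each run's best mask. Variants are compared with a
two-sided paired Wilcoxon signed-rank test at `α = 0.05`, verdict `+`/`−`/`=`
from the perspective of the first argument. Paired best fitnesses tie
often, and `stats::wilcox.test` declines exact p-values under ties, so for
up to 50 non-zero pairs the exact null distribution of the rank sum is
computed by dynamic programming (midranks for ties); larger samples fall
back to the normal approximation. Zero differences are dropped, as in the
standard procedure.

## Problem sizes

The published protocol is 100 repeats of 100 iterations with 30 agents per
dataset. The package defaults to 10 repeats at the same 5 × 6 × 100 agent
geometry — a deliberate desk-scale profile that keeps a full two-variant
experiment on a 200-gene planted dataset in the minutes range; pass
`n_repeats = 100` to `experiment_config()` for the full profile. Test and
acceptance workloads use 10–200 genes and 30–60 samples, sizes at which
planted-gene recovery and oracle attainment are informative yet quick.

## Worked example

```{r, eval = FALSE}
library(bpofs)

spec <- synthetic_spec(n_samples = 60, n_features = 200, n_informative = 5,
                       effect_size = 2, seed = 1)
truth <- synth_expression(spec)$informative

cfg <- experiment_config(spec, variant = "v",
                         po = po_config(dimensions = 1, max_iterations = 100),
                         fitness = fitness_config(),
                         n_repeats = 10, base_seed = 100)
runs <- run_experiment(cfg)
summarize_runs(runs)
sapply(runs, function(r) sum(truth %in% which(r$best_mask == 1)))
```

## Known limitations

* The generator's Gaussian class-shift model understates the difficulty of
  real expression data (no batch structure, no correlated noise).
* Wrapper selection is classifier-specific: a subset tuned for 5-NN is not
  guaranteed optimal for other classifiers.
* The fitness rewards sparsity linearly; with very small `nf` the sparsity
  term can dominate accuracy differences between near-tied subsets.
* KNN cross-validation dominates runtime; datasets in the tens of
  thousands of genes are feasible per run but slow under 100 repeats.
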