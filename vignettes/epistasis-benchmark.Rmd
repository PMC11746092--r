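---
title: "Simulating and benchmarking genotype risk models under epistasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and benchmarking genotype risk models under epistasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibench)
```

## The problem

Polygenic risk scores (PRS) weight individual SNPs additively on the
logit scale and therefore cannot represent *statistical epistasis* —
joint effects of several loci that are not a sum of per-locus effects.
`epibench` provides a controlled laboratory for asking when that matters:
it generates case-control cohorts whose disease probability interpolates
between a purely polygenic (logistic-linear) component and a purely
epistatic component defined by a penetrance table, and benchmarks linear
against non-linear classifiers on those cohorts under one fixed
evaluation protocol.

## The generative model

Each individual carries genotypes $x_i \in \{0, 1, 2\}$ (minor-allele
counts). Disease probability mixes two parts with a weight
$\alpha \in [0, 1]$:

$$
P(Y = 1 \mid x) \;=\; \alpha \, P_{\mathrm{lin}}(Y = 1 \mid x_1, \ldots, x_k)
\;+\; (1 - \alpha) \, P_{\mathrm{epi}}(Y = 1 \mid x^e_1, \ldots, x^e_L),
$$

where the linear part is an ordinary logistic model

$$
P_{\mathrm{lin}}(Y = 1 \mid x) =
\frac{\exp(\beta_0 + \textstyle\sum_i \beta_i x_i)}
     {1 + \exp(\beta_0 + \textstyle\sum_i \beta_i x_i)},
\qquad \beta_i \sim \mathcal N(0,\, 0.5),
$$

and the epistatic part is a table lookup: a *penetrance table* assigns a
disease probability to each of the $3^L$ genotype combinations of the
$L$ interacting loci ($L = 2$ or $3$). $\mathcal N(0, 0.5)$ is read as
standard deviation 0.5 (variance 0.25); the intercept is drawn from the
same distribution as the coefficients. Both choices are configurable
(`sample_linear_model()`).

At $\alpha = 1$ the phenotype is purely polygenic; at $\alpha = 0$ it is
pure epistasis. Genotypes are sampled independently per SNP under
Hardy-Weinberg equilibrium; the base design fixes genotype frequencies
at $0.25 / 0.5 / 0.25$ (i.e. MAF $0.5$) for non-causal and linear-effect
SNPs, while causal-locus MAFs come from the penetrance table.

## Penetrance tables and the heritability solver

Three classical two-locus interaction forms are supported, parameterised
on the penetrance (probability) scale by a baseline $a > 0$ and an
effect $\theta \ge 0$, with $g_1, g_2$ the minor-allele counts:

* **additive** — $p(g_1, g_2) = a\,(1 + \theta)^{g_1 + g_2}$: risk grows
  with every causal allele, within and between loci;
* **multiplicative** — $p = a$ unless both loci carry at least one
  causal allele, in which case $p = a\,(1 + \theta)^{g_1 g_2}$;
* **threshold** — exactly two risk levels: $a$ and $a\,(1 + \theta)$,
  the higher one when both loci carry a causal allele.

Three-locus tables extend these by summing (additive) or multiplying
(multiplicative) all allele counts and by requiring *all* loci to carry
a causal allele. Any parameter pair driving a cell above 1 is rejected
with an error naming the offending genotype: this feasibility constraint
is the reason the tables are built on the probability scale rather than
an odds scale — on the odds scale every positive parameter pair is
feasible, and the prevalence-maximisation below becomes degenerate
(effect growing without bound, the multiplicative form collapsing onto
the threshold form). On the probability scale the constraint $p \le 1$
is active and pins down a unique, well-behaved solution.

Summary statistics follow the observed-scale (0/1 trait) conventions of
epistasis simulators:

$$
\pi = \sum_g P(g)\, p_g, \qquad
h^2 = \frac{\sum_g P(g) (p_g - \pi)^2}{\pi (1 - \pi)},
$$

with $P(g)$ the Hardy-Weinberg product across loci. This is *not*
liability-scale heritability; a deterministic 0/1 trait has $h^2 = 1$.

`solve_penetrance(form, mafs, target_h2)` inverts the map: it finds
$(a, \theta)$ whose table attains a requested heritability. One
constraint against two parameters leaves a one-dimensional family; the
solver returns its member with **maximum prevalence subject to all
penetrances $\le 1$**. Along the heritability contour prevalence is
strictly decreasing in the effect, so the maximum sits at the smallest
feasible effect — the point where the largest penetrance cell equals
exactly 1. That reduces the problem to a bracketed one-dimensional
root-find on $\log \theta$ with $a = (1+\theta)^{-e_{\max}}$, solved to
a heritability residual below $10^{-10}$ (the contract guarantees
$10^{-6}$). Because the boundary family approaches a deterministic 0/1
trait as $\theta \to \infty$, every target $h^2 \in (0, 1)$ that is
numerically representable is reachable; the infeasibility error reports
the maximum achievable value when a target exceeds the searchable range.

Solved at $h^2 = 0.25$ and MAF $0.25$, the three forms have theoretical
AUC ceilings of about $0.889$ (additive), $0.777$ (multiplicative) and
$0.697$ (threshold) — the benchmark's reference points.

## Balanced cohorts and the replicate design

`balanced_dataset()` rejection-samples individuals (draw effect-locus
genotypes, evaluate the mixed probability, draw a Bernoulli label) until
exactly $n/2$ cases and $n/2$ controls are collected, then fills in the
non-causal noise SNPs. Exact 50/50 quotas — rather than "approximately
balanced" — remove one uncontrolled source of replicate variance.
Because class-conditional genotype distributions are unchanged by
balanced resampling, AUC-type quantities are comparable across
prevalences. An error is raised when the rarer class's acceptance
probability falls below $10^{-4}$.

The replicate benchmark (`gametes_experiment()`,
`run_gametes_benchmark()`) solves one table per form and generates
independent balanced cohorts of pure epistasis ($\alpha = 0$): by
default 2 causal loci hidden among 998 noise SNPs, 20,000 individuals
per replicate. The alpha sweep (`alpha_sweep()`, `run_alpha_sweep()`)
instead fixes *one* genotype matrix and draws one label vector per
$\alpha$ on a grid (default: 10 evenly spaced values from 1 to 0,
endpoints included — the grid spacing is a package choice), so that the
phenotype family differs only in how much of the risk is epistatic. The
sweep's default epistatic component is a three-locus threshold table:
its max-prevalence solution sits near prevalence $0.5$, which keeps
every label vector of the sweep close to class balance without
rejection sampling.

All randomness descends from one integer root seed through named
sub-streams (genotypes, coefficients, labels, splits, minibatch
shuffling), so every experiment replays exactly.

## Theoretical AUC

For data generated by the model itself, no classifier can beat the
ground-truth probability $s(g) = P(Y=1 \mid g)$ used as a score. Its
AUC has a closed form over the genotype classes:

$$
\mathrm{AUC} = \frac{\sum_{i,j} P_i P_j \, s_i (1 - s_j)
  \left[\mathbf 1(s_i > s_j) + \tfrac12 \mathbf 1(s_i = s_j)\right]}
  {\pi(1 - \pi)}.
$$

`theoretical_auc()` evaluates this exactly by enumerating the effect-SNP
genotype classes (refusing beyond $10^6$ classes) or by Monte Carlo.
The exact path aggregates duplicate scores at 14 significant digits and
accumulates the pair sum via a single cumulative pass, so it matches a
literal all-pairs oracle to machine precision. Every trained model's
test AUC is checked against this ceiling in the test suite.

## Classifiers and the training protocol

Seven families sit behind one `build_classifier()` /
`fit_classifier()` / `predict_proba()` contract, all consuming the
one-hot encoding (three indicator columns per SNP, ordered by SNP then
genotype level):

* `lasso_logistic` — L1-penalised logistic regression (glmnet). The
  penalty is selected on the training portion by 4-fold
  cross-validation over a logarithmic grid $10^{-4} \ldots 10^{1}$
  (AUC criterion), so the linear baseline is always competently tuned.
* `random_forest` — ranger, 500 trees, probability forests.
* `gradient_boosting` — xgboost, 500 trees, histogram method,
  library-default depth 6. The boosted-trees family is the package's
  non-linear reference model.
* `mlp`, `cnn`, `rnn`, `rnn_cnn` — run on the package's own
  matrix-based neural engine: dense, batch-normalisation, dropout, 1-D
  convolution and LSTM layers with analytically derived backward passes
  (each validated against finite differences in the test suite). The
  MLP has three hidden layers (search bounds 300-2500 / 100-500 /
  10-75) with batch-norm, ReLU and dropout; the CNN two 1-D
  convolutions (channels 150-1000, kernel and stride 1-4) over the
  3-channel per-SNP layout plus one fully connected hidden layer
  (50-100); the RNN one LSTM (hidden 50-300, dropout 0.7-0.9) over the
  SNP sequence; the hybrid chains LSTM, two convolutions and a dense
  hidden layer. Out-of-range architectures raise a configuration error
  unless `strict = FALSE`.

Neural training uses Adam on binary cross-entropy (computed on logits),
a cosine-annealed learning rate cycling from $10^{-3}$ down to
$10^{-4}$ every 10 epochs, minibatches of 256, and early stopping once
validation loss has risen for more than 5 consecutive epochs; the
checkpoint with the best validation AUC-ROC is restored. Batch size and
the epoch budget (default 30) are package defaults — exposed in
`training_protocol()` — chosen so that the default MLP converges on the
benchmark cohorts before the budget binds. The early-stopping counter
reads the *validation* loss, consistent with best-on-validation
checkpointing. The default MLP regularisation (dropout 0.7 after the
input layer, 0.5 after the hidden layers) is the configuration a
validation-AUC grid search selects on the benchmark cohorts, where the
3,000-feature input invites rapid overfitting; `grid_search()` runs the
full Cartesian search when a grid with several candidates is supplied.

`grid_search()` evaluates the Cartesian hyperparameter grid exhaustively
and selects by validation AUC-ROC, breaking ties in favour of the
earlier configuration.

## Evaluation protocol

`cross_validate()` implements *repeated stratified holdout* (the term
"cross-validation" is avoided in the documentation to prevent confusion
with k-fold): per cycle a fresh stratified 60:40 train/test split;
five cycles by default. Neural families split the 40% holdout equally
into a validation half (selection, early stopping, checkpointing) and
an independent test half, and are scored on the test half only;
linear and tree families use the full 40% as test, resolving their
hyperparameters internally on the training portion. Splits are
stratified by class — the balanced designs then keep both classes in
every partition and one source of cycle-to-cycle variance disappears.

Metrics: accuracy, precision, recall and F1 at a probability threshold
(default 0.5, precision defined as 0 when nothing is predicted
positive); AUC-ROC as the Mann-Whitney rank statistic with half credit
for ties; AUC-PR by step-wise integration of the precision-recall curve
without interpolation (implementations differ here, so the convention
is fixed and tested). Aggregates are per-metric mean, standard
deviation and a normal-approximation 95% confidence interval
$\bar m \pm 1.96\, s/\sqrt{\text{cycles}}$. `replicate_summary()` then
averages report means across replicate datasets into the benchmark
table (mean ± sd per family and metric).

## What the generator does and does not emulate

The simulation captures: Hardy-Weinberg genotypes, pure and mixed
epistatic architectures with controlled heritability, balanced
case-control ascertainment, and causal loci hidden among noise SNPs.
It deliberately omits linkage disequilibrium, population structure,
genotyping error, missingness and continuous phenotypes — SNPs are
independent by construction. Conclusions drawn from passing tests
therefore concern the *statistical* ability of model families to
represent interaction effects, not the practical discoverability of
epistasis in real cohorts, where LD and ascertainment noise interfere.

One structural property of these interaction forms deserves emphasis:
for a threshold-form table the optimal *additive-in-indicators* score
already ranks every high-risk cell above every low-risk cell (ties
among equal-penetrance cells cost nothing in AUC), so a well-tuned
one-hot lasso can in principle approach the same ceiling as a
non-linear model; observed linear-vs-non-linear gaps on such tables are
finite-sample effects of penalised estimation with thousands of noise
features rather than representational limits. A truly linear-blind
signal requires nulled marginals (the exclusive-or fixture in the test
suite, where the lasso stays at AUC 0.5 while boosted trees learn the
interaction). This is why the benchmark's linear/non-linear gaps are
smaller than those a weakly tuned linear baseline would show.

## Problem sizes used by the automated runs

The test suite and the acceptance script run desk-scale versions of the
two studies, a package choice to keep the default runs small: the
replicate benchmark uses 3 replicates per form (20,000 x 1,000 as in
the full design) with one holdout cycle each; the MLP is evaluated with one 60:20:20 cycle per
threshold replicate and a 25-epoch budget; the alpha sweep runs
$\alpha \in \{1, 0.5, 0\}$ at $n = 10{,}000$ with 100 SNPs. The
full-scale protocol (10 replicates, 5 cycles, the complete neural grid)
is available through `experiment_config()`.

## Numerical choices

* Heritability solver: root-find tolerance $10^{-10}$ on the residual,
  bracket located on a 400-point log-spaced effect grid spanning
  $10^{-9} \ldots 10^{9}$.
* AUC ties: half credit, consistently in the rank statistic, the exact
  enumeration and the brute-force test oracle.
* Exact theoretical AUC: score classes merged at 14 significant digits.
* Batch normalisation: momentum 0.9, $\epsilon = 10^{-5}$, running
  statistics updated in training mode only; batches of size 1 are
  skipped.
* Dropout: inverted scaling at train time, identity at prediction.
* LSTM: forget-gate bias initialised to 1; uniform
  $\pm 1/\sqrt{H}$ weight initialisation; dense/conv layers use He
  initialisation.
* Degenerate inputs: monomorphic loci (MAF 0) are legal in genotype
  sampling but not in penetrance tables (MAF must be positive);
  single-class label vectors make AUC metrics raise an error rather
  than return a default.

## Known limitations

* The neural engine is CPU-bound base R; it is adequate for the
  benchmark's cohort sizes but not for genome-scale inputs.
* Boosted trees are provided through one backend (xgboost); the
  boosted-trees family abstraction accepts per-family spec overrides,
  but no alternative in-process backend ships with the package.
* The exact theoretical AUC enumerates genotype classes and refuses
  beyond $10^6$; mixed models with many linear SNPs fall back to Monte
  Carlo.
* Penetrance tables cover the three named interaction forms (orders 2
  and 3); arbitrary user-defined epistasis formulas are out of scope,
  though explicit tables can be constructed directly with
  `penetrance_table()`.

## A worked miniature

```{r mini, eval = FALSE}
tab <- solve_penetrance("threshold", c(0.25, 0.25), 0.25)
prevalence(tab)       # ~0.486
heritability(tab)     # 0.25

model <- mixed_phenotype_model(0, sample_linear_model(0, seed = 0),
                               tab, integer(0), 1:2)
theoretical_auc(model)  # ~0.697: the ceiling for any classifier

exp <- gametes_experiment("threshold", replicates = 1, n = 4000,
                          total_snps = 50, seed = 7)
spec <- classifier_spec("gradient_boosting",
                        grid = list(nrounds = list(300L),
                                    max_depth = list(6L)))
cross_validate(spec, exp$datasets[[1]], cycles = 2, seed = 7)
```
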