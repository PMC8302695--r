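---
title: "Constrained Bayesian networks for disentangling syntrophic electron transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained Bayesian networks for disentangling syntrophic electron transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methanet)
```

## The scientific problem

Methanogenic communities dispose of fermentation electrons through two
competing syntrophic routes. In interspecies hydrogen transfer (IHT),
fermenters and *Geobacter*-like partners evolve H~2~ that hydrogenotrophic
methanogens (e.g. *Methanobacterium*) oxidize through the
MvhADG/HdrABC electron-bifurcation complex. In direct interspecies electron
transfer (DIET), electrons pass through extracellular electron transfer
(EET) machinery — outer-membrane *omc* cytochromes and conductive *pilA*
pili — possibly into methanogen polyferredoxins (*mvhB*). The two routes
are hard to separate experimentally because the same organisms carry genes
for both.

`methanet` addresses the question statistically. It learns a directed
dependency network over multi-omic feature tables (16S rRNA gene
abundances, 16S rRNA activities, per-gene RPKM expression, reactor
performance variables), constrained so that inference can only flow from
fermentative bacteria and *Geobacter* over methanogens to CH~4~
production. The network is validated by leave-one-out cross-validation and
then interrogated with in-silico gene knockouts: silencing all
IHT-labelled genes (ΔIHT) or all DIET-labelled genes (ΔDIET) and measuring
how much predictive power for methane production is lost.

## The model

Each variable is min-max rescaled to $[0,1]$,
$v^{\mathrm{norm}}_{ij} = (v_{ij} - \min_j)/(\max_j - \min_j)$,
and modeled as a linear-Gaussian Bayesian network: every node equals an
intercept plus a weighted sum of its parents plus Gaussian noise, so the
joint distribution is multivariate normal. Structure is learned by greedy
hill climbing on the Gaussian BIC score

$$\mathrm{BIC}(G) = \sum_{v} \left[ \hat\ell_v - \tfrac{k_v}{2}\ln n \right],
\qquad k_v = |\mathrm{pa}(v)| + 2,$$

where $\hat\ell_v$ is the maximized Gaussian log-likelihood of $v$ given
its parents (OLS fit, ML residual variance $\mathrm{RSS}/n$). Parameters of
the selected graph are the per-family maximum-likelihood estimates.

Why these choices:

* **Score.** The continuous-data default of the hill-climbing tool this
  package mirrors is the Gaussian BIC with the $\ln(n)/2$ penalty; the
  score is decomposable by node, which the search exploits.
* **Constraints.** The tier blacklist forbids every edge from a strictly
  later tier to a strictly earlier one ({fermenter, geobacter} →
  methanogen → output) and every edge out of the output; environment
  variables are unranked but never receive edges from the output.
  Fermenter and *Geobacter* form one tier class, so edges between them are
  unconstrained by default (`allow_within_tier` switches within-class
  edges off).
* **Search.** Deterministic greedy search from the whitelist-only graph
  with add/delete/reverse operators and a lexicographic tie-break on
  (operator kind, parent name, child name); operator gains that agree to
  within rounding error count as ties, which matters because the two
  orientations of a single edge are score-equivalent. Random restarts are
  off by default (determinism first) but available and seeded.
* **Variance floor.** Residual variances are floored at $10^{-12}$ so
  interpolating fits keep finite log-likelihoods, and a family whose
  parameter count would exceed the fold's sample size scores $-\infty$,
  which caps parent sets at $n-2$.

## Validation

`loo_cv()` retrains structure and parameters on every $n-1$ subset and
predicts the held-out sample. Two prediction mechanisms are provided,
because the right one is a genuine modeling decision: `"parents"`
evaluates each target's local regression (requires the target's parents
observed — appropriate for predicting CH~4~ from gene evidence), and
`"joint"` conditions the implied multivariate Gaussian on all observed
evidence (appropriate for reconstructing the whole community from the
environmental variables). Every report records which method was used.

Reconstructions are scored by the mean per-sample Bray–Curtis similarity
$1 - \sum_k |u_k - v_k| / \sum_k (u_k + v_k)$ against the
average-abundance null model (each target predicted as its training-fold
mean), by squared Pearson correlation, and by relative RMSE
$\sqrt{\tfrac1n\sum_i (y_i - t_i)^2} / y_{\max}$. All three are computed on
the normalized modeling scale; negative predictions are clipped to zero
before Bray–Curtis, since the metric is undefined for negative masses.

Two definitional quirks are worth knowing. First, the squared-Pearson
$R^2$ of the *null* model is identically 1: a leave-one-out mean is an
affine (decreasing) function of the held-out value. Its relative RMSE and
Bray–Curtis are the meaningful null comparisons, and the regression-based
coefficient of determination is available as `r_squared(..., method =
"cod")`. Second, the Bray–Curtis of two all-zero profiles is defined as 1
(identical emptiness) with a warning.

## The in-silico knockout

`silence_genes()` sets the listed expression columns to zero, the
operational definition of a knockout here. The default `"retrain"` mode
silences the genes in the data, drops the resulting constant columns, and
reruns the entire learning + LOO-CV pipeline, because the silencing is an
intervention on the *input* data; `"evidence_only"` keeps the complete
model and only zeroes evidence at prediction time. The two modes agree on
which mechanism matters more (a tested property), though magnitudes
differ. "Significance" of a knockout effect is operationalized as a
seed-resampled sign test across simulation replicates — an artifact
convention, not a reconstruction of any published test.

## What the synthetic generator emulates

Real sequencing data for this system live under a GenBank accession and
are not shipped; the generator reproduces the *statistical structure* the
analysis assumes, so every stage is testable offline.

* **Gene cascade** (`build_template_sem()`): a fixed-topology
  linear-Gaussian structural equation model with four fermenter genes
  (adhE-, dhaT-like alcohol genes; hyaB-, hox-like H~2~-evolving genes),
  four *Geobacter* genes (omcF-, pilA-like EET/DIET nodes; hnd-, ech-like
  hydrogen-cycling IHT nodes), three methanogen genes (mvhADG-,
  hdrABC-like IHT nodes and an mvhB-like DIET node) and one CH~4~ output.
  Every IHT-labelled path into the methanogen tier carries weight
  `iht_effect`, every DIET-labelled path `diet_effect`. Three disconnected
  distractor genes provide a null intervention target. Guild-level gene
  nodes carry unit intrinsic noise — each gene has regulation of its own
  that upstream genes do not explain — while `noise_sd` (default 0.2)
  controls the residual noise of the integrating methanogen tier and the
  output. Without that separation a silenced gene set would be almost
  perfectly proxied by its exogenous drivers and knockouts would lose
  their meaning.
* **Expression tables** (`simulate_expression()`): ancestral sampling in
  topological order, then a per-column *shift* (never truncation) to
  non-negativity, so the closed-form SEM covariance remains exact and
  serves as a test oracle.
* **Community tables** (`simulate_community()`): latent per-taxon
  activities follow a fermenter → *Geobacter* → methanogen cascade with
  strength `community_effect`; relative abundances arise by softmax-style
  closure of exponentiated latents with a remainder bucket, guaranteeing
  non-negative rows summing below one while keeping a near-linear core
  for the network to find. The 22 designated core taxa pass the > 0.5 %
  mean abundance / > 50 % occurrence rule by construction; distractor
  taxa are orders of magnitude rarer and drop out of most samples. Nine
  environmental parameters (CH~4~ production first) are linear in
  designated latent activities with strength `env_effect`; setting both
  effects to zero yields an independence fixture on which the network
  must *not* beat the null model.
* **Count fixtures** (`simulate_counts()`): Poisson read counts with
  recorded gene lengths and mapped-read totals, for exercising the RPKM
  arithmetic end to end.

Defaults encode the study conditions: 24 samples (the metatranscriptomic
design of eight reactors × three replicates over two batches), a strong
hydrogen path (`iht_effect = 0.8`) against a weak direct path
(`diet_effect = 0.2`), `noise_sd = 0.2`. One master seed drives a hash-based
hierarchy of per-table seeds (`derive_seed()`), so regenerating one table
never shifts another's random stream.

What the generator does **not** emulate: sequencing read noise, chimeras,
compositional count overdispersion (multinomial/Dirichlet), taxonomic
misassignment, or reactor dynamics over time. Passing tests therefore
demonstrate correctness of the algorithms under the linear-Gaussian,
compositionally-closed assumptions — not robustness to every artifact of
real amplicon or metatranscriptomic data.

## Numerical and degenerate-input conventions

* Constant columns normalize to 0 (Eq. undefined there; matches the
  knockout convention) with a warning, and `drop_zero_variance()` removes
  them before learning.
* Core-population thresholds are strict inequalities, and occurrence
  counts a sample at abundance > 0 exactly (no detection floor).
* Selection precedes normalization; thresholds apply to raw relative
  abundances. Normalization is computed on the assembled matrix, not per
  source table.
* Collinear parents make a family score $-\infty$ during search and raise
  a named error in `fit_mle()`.
* Ties in the search are broken lexicographically; identical inputs give
  identical outputs on any platform, and results do not depend on column
  order.

## Known limitations

* Greedy search with lexicographic tie-breaks fixes the orientation of
  score-equivalent edges by name order; when a v-structure's collider
  child is unluckily named the search can lock the wrong orientation and
  stop in a local optimum. Seeded random restarts
  (`hill_climb(restarts = )`) escape such optima more often than plain
  greedy — a tested property — at the cost of extra runs.
* ML-BIC at very small fold sizes ($n \lesssim p$) produces dense,
  overfit families up to the $n-2$ parent cap; interpret networks learned
  from tens of samples structurally, not causally.
* Squared Pearson as the default $R^2$ is affine-invariant and therefore
  blind to calibration; relative RMSE covers the scale.
* The knockout ranks *predictive* contributions under the tier
  constraints; it is not interventional do-calculus.

## Problem sizes used by the shipped checks

The package's own test suite and the reproduction script run entirely on
synthetic data at the following sizes, chosen to exercise the study
conditions while keeping a full run in minutes on one CPU: knockout
contrast at $n = 200$ samples over 20–50 replicate communities; community
reconstruction at $n = 24$ samples (22 core taxa + 9 environmental
parameters) over 10–20 replicates; structure-recovery checks on 100
three-node problems at $n = 200$ against exhaustive enumeration; parameter
recovery at $n = 1000$.
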