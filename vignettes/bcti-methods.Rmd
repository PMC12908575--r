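---
title: "Methods: network scoring, search, and critical-transition detection in bcti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network scoring, search, and critical-transition detection in bcti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcti)
```

## Overview

`bcti` treats an ordered series of expression matrices (tumor stages,
developmental time points, a swept control parameter) as snapshots of a
time-varying gene regulatory network. At each stage it learns a directed
acyclic network by score-based Bayesian structure search, and it reads the
trajectory of the optimal network's score as an early-warning signal for a
critical transition. This vignette documents the model, every tunable
parameter, the numerical choices, and what the bundled synthetic
generators do and do not emulate.

## The skeleton: Gaussian mutual information

For genes $X_i, X_j$ with Pearson correlation $\rho_{ij}$, the mutual
information under a bivariate Gaussian assumption has the closed form

$$I(X_i, X_j) = -\tfrac{1}{2}\log\!\left(1 - \rho_{ij}^2 + \varepsilon\right),$$

in nats (natural logarithm throughout the package). The guard
$\varepsilon = 10^{-5}$ keeps the value finite as $|\rho| \to 1$; its side
effect is a slightly negative value ($\approx -5\times10^{-6}$) at
$\rho = 0$, which is harmless at any positive threshold. A pair is an edge
of the undirected *correlation basis network* (CBN) iff $I \ge T$ with
default $T = 0.1$, equivalent to $|\rho| \gtrsim 0.4258$. The CBN is
computed per stage: each time point gets its own skeleton, since the
network is assumed to rewire over time. A gene with zero variance within a
stage has no defined correlation; it is treated as independent of
everything (with a warning), matching the thresholding rule's fallback.

The discrete (binned) mutual-information estimator is deliberately not
implemented; the Gaussian closed form replaces it wholesale. No partial
correlations or background corrections are applied — the CBN is a
permissive candidate set, not the final network.

## The score: structural equations with an MDL penalty

Each node is modelled as an intercept-free linear combination of its
parents plus Gaussian noise. On data centered within the stage, the local
score of node $s$ with parent set $Pa(s)$ is

$$\text{local}(s) = F_s + \lambda\,|Pa(s)|\,\log n, \qquad
  F_s = \sum_{v=1}^{n}\left(x_{sv} - \hat\theta_s\, x_{Pa(s),v}\right)^2,$$

with $\hat\theta_s$ the least-squares estimate, and the network score
$H(G)$ is the sum of local scores. $H$ is decomposable: an edge change
rescores only the touched nodes, which the search exploits.

Numerical choices:

* **Centering, not standardizing.** The model has no intercept, so each
  gene's row is mean-centered within the stage (`center_genes = TRUE`).
  Rows are *not* scaled to unit variance: $H$ grows with expression
  variance (for fixed structure, scaling centered data by $c > 1$ strictly
  increases $H$ whenever any residual is nonzero), and that variance
  sensitivity is exactly the early-warning mechanism. Standardizing would
  erase it.
* **Minimum-norm least squares, no ridge.** Rank-deficient or
  ill-conditioned designs (duplicated parents, $p \ge n$, the strong
  co-variation that appears near a transition) get the pseudoinverse
  solution via the singular value decomposition (singular values below
  $10^{-12}$ of the largest are treated as zero). The residual is always
  well-defined. Regularizing the collinearity away would mask the search
  instability that the detector uses as corroborating evidence, so no
  penalty on $\theta$ is applied.
* **$\lambda = 1$ by default** (exposed as `lambda_reg`), which reduces
  the penalty to the familiar BIC-like $|Pa|\log n$. The log base is
  natural, consistently with the mutual-information units.

## The search: CBN-constrained restart hill climbing

From a random initial DAG the climber repeatedly forms the three
single-edge move categories — additions (either orientation of a CBN pair
absent from the DAG), deletions, reversals — takes the best move of each
category, compares the three winners, and accepts the overall winner iff it
lowers $H$ by more than `improvement_tol` ($10^{-9}$, absolute; this is a
float-churn guard, not a model parameter). Additions and reversals are
filtered by an incremental depth-first reachability check so every state is
a DAG, and only CBN pairs are ever candidates. The climb terminates at the
first iteration with no accepted move (or at `max_iterations = 1000`, with
a warning — not observed at the problem sizes below).

* **Initial DAGs.** A uniform random topological order is drawn; each CBN
  edge is included independently with probability `init_edge_prob = 0.5`
  and oriented along the order. This guarantees acyclicity and skeleton
  conformance and diversifies restarts.
* **Restarts.** `n_restarts_I = 10` independent climbs; the minimum-$H$
  result is returned, with per-restart scores and networks kept for the
  consistency diagnostic. All randomness derives from one integer seed via
  a deterministic per-stage, per-restart derivation, so results are
  bit-reproducible from (data, parameters, seed).
* **Tie-breaks.** Candidate moves are scanned in lexicographic order
  (kind with add < delete < reverse, then source id, then target id) and
  only strict improvements replace the incumbent, so argmin ties resolve
  deterministically; restart ties resolve to the earliest restart.
* **Incremental scoring.** Local scores are memoised per (child,
  parent-set); a move evaluates at most two fresh fits. Equality of
  incremental and full rescoring along random move sequences is enforced
  by the test suite.

## Detection: the score trajectory and the dual criterion

$S(t)$ is the $H$ score of stage $t$'s optimal network. At each stage
$t \ge 3$ a one-sample t-test takes the history $S(1), \dots, S(t-1)$ as
the sample and $S(t)$ as the hypothesised mean ($t - 2$ degrees of
freedom); the earliest stage with $p < \alpha$ (default 0.05) is called
critical. Two-sided by default; a one-sided `"greater"` option exists
because the theory predicts a score *rise*. A zero-variance history is
degenerate: $p = 1$ if the current score equals the historical value
(within $10^{-12}$), else $0$ — this makes the noise-free simulator limit
(identical replicates, flat zero scores) silent rather than
false-positive.

The second arm of the dual criterion is structural instability: restart
consistency (mean pairwise Jaccard of restart edge sets; two empty sets
count as agreeing) and, when a reference network is supplied, the
true-positive rate against it. Both are reported as *corroboration* of the
score-based call, not as a gate: the score test is the primary criterion,
and instability distinguishes a genuine approach to a transition from an
isolated scoring anomaly.

Two caveats are worth stating plainly. First, the earliest testable stage
($t = 3$) has one degree of freedom, so its test is heavy-tailed and
retains roughly its nominal false-positive rate; with short histories an
early spurious call is possible and the corroboration flag is the guard.
Second, raw $H$ sums over samples, so stages with more samples score
higher mechanically. Default behaviour keeps raw scores; `equalize_n`
subsamples every stage to the minimum stage size with a seeded draw when
stage sizes differ materially. Neither behaviour is imposed silently.

## The synthetic generators

### Planted-transition fixtures

`generate_planted_transition()` emulates the two signatures of an
approaching transition in a stage-wise dataset: inflated per-gene variance
and inflated inter-gene correlation inside a core subnetwork, at one
designated critical stage. Defaults (20 genes, 6 stages, critical stage 4,
50 samples per stage, variance inflation 4, correlation boost 0.6, an
8-gene core with a 7-edge regulatory tree, $\beta = 0.8$) define the
standard test conditions.

Off-transition, core genes follow the linear SEM over the true edges with
a *constant* noise sd (`baseline_sd = 1`), so variance accumulates along
regulatory depth. The unequal variances matter: they make edge orientation
identifiable by the score, so pre-transition restarts agree on a stable
structure, and the consistency *drop* at the critical stage is a real
contrast rather than noise on top of ubiquitous orientation ambiguity. At
the critical stage all noise sds are multiplied by
$\sqrt{\text{inflation}}$ and a shared standard-normal latent factor is
added to core gene $i$ with loading $\sqrt{c\,v_i}$, where
$c = \frac{\text{boost}}{1-\text{boost}}\,\text{inflation}$ and $v_i$ is
the gene's off-transition variance; every unrelated core pair then has
expected correlation exactly `correlation_boost` (related pairs higher).

What the fixture does *not* emulate: counts/heteroscedastic noise of real
RNA-seq, library-size and batch effects, nonlinear regulation, latent
confounders outside the core, or stage-to-stage sample overlap. Passing
tests on these fixtures show that the pipeline detects the planted
signature under its own model assumptions, not that it is robust to the
full messiness of real transcriptomes.

### The bifurcating Michaelis–Menten circuit

`simulate_mm_sde()` integrates
$dx_i = \big[b_i + \sum_{j \to i} \mathrm{MM}(x_j) + q - d_i x_i\big]dt
+ \sigma\, dW$ by Euler–Maruyama (default $dt = 0.01$) with states
reflected at zero, where activation contributes
$V x^h/(K^h + x^h)$ and inhibition $V K^h/(K^h + x^h)$ (Hill $h = 2$).
The control parameter $q$ enters every node's drift additively and sweeps
$[-0.3, 0.3]$; each grid value is one output stage whose samples are
replicate endpoint states after a burn-in of `n_steps_per_q` steps
(default 10,000, i.e. 100 time units — chosen because the slowest mode
near the bifurcation relaxes at rate $\sim\sqrt{|q|}$ and shorter burn-ins
leave the near-critical variance unequilibrated).

The default 16-node fixture is a synthetic stand-in whose parameters are
its own documentation: genes g01/g02 mutually activate with $V = 2Kd$
($K = 90$, $d = 1$) and a basal rate solved from the tangency condition so
the low-expression branch undergoes a saddle-node bifurcation exactly at
$q = 0$; 14 downstream genes ($V = 10$, $K = 15$, basal 2, $d = 1$) form a
signed cascade. Approaching $q = 0^-$ the driver's restoring rate shrinks
like $\sqrt{-q}$, endpoint variance inflates (critical slowing down, with
noise-driven excursions to the high branch near the fold), and the
stage score surges — the qualitative early-warning behaviour the detector
is designed to see. No claim is made that these rate constants reproduce
any external benchmark's trajectories.

## Evaluation conventions

Confusion counts are taken over all $m(m-1)$ ordered gene pairs excluding
self-pairs, and matching is direction-sensitive: a reversed edge is one
false positive plus one false negative. $\mathrm{TPR} = TP/(TP+FN)$
(undefined, an error, for an empty gold standard) and accuracy
$=(TP+TN)/(m(m-1))$; a precision-style alternative $TP/(TP+FP)$ is
available via `accuracy(type = "precision")`.

## Problem sizes and runtime choices

The test suite and acceptance script run at desk scale by design: oracle
comparisons exhaustively enumerate structures for 2–4 genes (at most
$3^{|\mathrm{CBN}|}$ orientation assignments); planted-transition checks
use 20 replicates of the 20-gene, 6-stage default; simulator checks use
200 replicates at two $q$ values plus one 8-value sweep at 50 replicates.
These sizes give stable Monte-Carlo estimates for the stochastic checks
while the whole suite completes in a few minutes on one core. The search
itself handles hundreds of genes; cost is dominated by candidate-move
evaluation, which the memoised incremental rescoring keeps near-linear in
the CBN size per iteration.

## Known limitations

* Linear, Gaussian, intercept-free structural equations; no nonlinear or
  discrete-variable scoring.
* Greedy search with restarts: optimality is only guaranteed empirically
  (and tested) at small scale; no tabu/annealing/order-based variants.
* Per-stage independence: stages are modelled separately, with no
  smoothness prior linking consecutive networks.
* The score test needs at least two history stages, inherits the raw
  score's dependence on sample size (see `equalize_n`), and is fragile at
  its first testable stage.
* Expression preprocessing (normalisation, log-transformation, variable
  gene selection) is upstream of the package and deliberately out of
  scope; the loader is agnostic to whether values are log-transformed.
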