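# bcti

Joint inference of gene regulatory networks (GRNs) and detection of
critical transitions from stage-wise expression data.

## The problem

Complex diseases and developmental programs often progress through a stable
*before-transition* state, a fragile *pre-transition (critical)* state, and
a second stable *after-transition* state. Near the tipping point a core
group of genes shows two early-warning features: sharply increased
expression fluctuations and strongly enhanced co-variation (the dynamic
network biomarker signature). Methods that only track those statistical
fluctuations say nothing about the regulatory structure behind them; static
GRN inference says nothing about the approach to a transition. `bcti`
couples the two: it infers a directed regulatory network at every stage of
an ordered series and uses the trajectory of the network's own score as the
early-warning signal.

## The model

At each stage, for genes `X_1, ..., X_m` with `n` samples:

1. **Skeleton.** Pairwise Gaussian mutual information
   `I(X_i, X_j) = -1/2 log(1 - rho_ij^2 + eps)` (natural log, `eps = 1e-5`
   guards the singularity at `|rho| = 1`) is thresholded at `T = 0.1` nats
   to give the undirected *correlation basis network* (CBN) that constrains
   the structure search.
2. **Score.** Each node is a linear, intercept-free structural equation of
   its parents, `x_s = theta_s x_Pa(s) + e_s`, fit by minimum-norm least
   squares on mean-centered data. The network score is the
   minimum-description-length sum
   `H(G) = sum_s [ F_s + lambda |Pa(s)| log n ]`,
   with `F_s` the residual sum of squares; lower is better.
3. **Search.** Restart hill-climbing over DAGs: add / delete / reverse
   single edges (additions and reversals restricted to CBN pairs,
   acyclicity enforced), accepting the best score-improving move until
   convergence; the best of `I` seeded restarts is the stage's optimal
   network.
4. **Detection.** The stage score `S(t) = H` of stage `t`'s optimal network
   is positively tied to expression variance, so it surges entering the
   critical state. The earliest stage `t >= 3` whose score differs
   significantly from the history `S(1), ..., S(t-1)` (one-sample t-test,
   `P < 0.05`) is called critical. Enhanced co-variation near the tipping
   point also makes the regression multicollinear and the search unstable,
   so a drop in restart consistency (mean pairwise Jaccard of restart edge
   sets) and in recovery of a reference network corroborate the call.

Benchmark generators ship with the package: a Michaelis–Menten
stochastic-differential-equation circuit swept through a saddle-node
bifurcation by a control parameter `q`, and a stage-wise
linear-SEM generator with a planted critical stage. Evaluation against gold
standards uses direction-sensitive confusion counts over ordered gene
pairs.

## Worked example

Generate a six-stage dataset with a planted critical stage 4 (20 genes,
50 samples per stage, variance inflation 4, correlation boost 0.6 in an
8-gene core), infer a network per stage, and call the critical state:

```r
library(bcti)
sim <- generate_planted_transition(planted_config(seed = 1))
ser <- compute_bcti_series(sim$data, search_params = search_params(seed = 1),
                           reference = sim$gold)
print(ser)
det <- detect_critical_state(ser)
```

```
<bcti_series>
 stage        S         p consistency    tpr
    S1  998.773        NA      0.7506 1.0000
    S2 1060.960        NA      0.6088 1.0000
    S3  919.410 0.1747000      0.5633 0.7143
    S4 2525.420 0.0007138      0.5056 1.0000
    S5 1079.390 0.4961000      0.6695 1.0000
    S6 1001.170 0.3570000      0.8578 1.0000
critical stage: S4
corroborated by instability: TRUE
```

`S` is the optimal-network score per stage: it roughly doubles at the
planted stage S4 and its t-test p-value (0.0007) is the only one below
0.05, so S4 is called critical. The first two stages have no p-value
(a score needs at least two history points to be testable). `consistency`
is restart agreement — lowest at S4, corroborating the call — and `tpr`
is recovery of the true planted edges by the stage network.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "bcti.R", package = "bcti")` with subcommands
`cbn`, `score`, `infer`, `detect`, `simulate`, `evaluate`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","bcti.R",package="bcti"))')" \
  infer --expr X.tsv --restarts 10 --seed 42 --out net.tsv
```

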