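# Benchmark data generators.
#
# (a) A small regulatory circuit with Michaelis-Menten kinetics integrated
#     as a stochastic differential equation (Euler-Maruyama, states
#     reflected at 0) while a control parameter q sweeps the system toward
#     a bifurcation at q = 0. Near the bifurcation the leading restoring
#     rate vanishes, so endpoint fluctuations across replicates inflate --
#     the critical-slowing-down signature the detector is built to see.
#
# (b) A stage-wise linear-SEM generator with a planted critical stage in
#     which a core subnetwork shows inflated noise variance and a shared
#     latent factor that raises pairwise correlations -- the two
#     dynamic-network-biomarker features, injected by construction.

#' Configuration for the Michaelis-Menten SDE simulator
#'
#' Regulatory interactions are Hill-type Michaelis-Menten terms: activation
#' contributes `V * x^h / (K^h + x^h)` and inhibition `V * K^h / (K^h + x^h)`
#' to the target's drift; each node additionally has a basal production
#' rate, linear degradation, and the additive control parameter q. Noise is
#' additive with strength `sigma_noise`.
#'
#' @param network `directed_network` of regulatory edges (cycles allowed;
#'   build with `require_acyclic = FALSE`).
#' @param edge_sign Numeric vector (+1 activation / -1 inhibition), one per
#'   edge of `network` in its edge order.
#' @param vmax,km Positive per-edge maximal rates and half-saturation
#'   constants, one per edge.
#' @param hill Hill coefficient (default 2).
#' @param basal,degradation Positive per-node basal production and
#'   degradation rates.
#' @param q_grid Ordered control-parameter values, within \[-0.3, 0.3\] by
#'   default convention; one output stage per value.
#' @param sigma_noise Non-negative noise strength.
#' @param dt Euler-Maruyama step (default 0.01).
#' @param n_steps_per_q Integration steps (burn-in) per replicate.
#' @param n_replicates Replicates per q value (the stage's sample count).
#' @param seed Integer seed.
#' @return A list of class `"sde_config"`.
#' @export
sde_config <- function(network, edge_sign, vmax, km, hill = 2,
                       basal, degradation,
                       q_grid = c(-0.30, -0.25, -0.20, -0.15, -0.10,
                                  -0.05, -0.02, -0.01),
                       sigma_noise = 0.5, dt = 0.01, n_steps_per_q = 10000L,
                       n_replicates = 50L, seed = 1L) {
  ne <- nrow(network$edges)
  m <- length(network$gene_ids)
  stopifnot(length(edge_sign) == ne, all(edge_sign %in% c(-1, 1)),
            length(vmax) == ne, all(vmax > 0),
            length(km) == ne, all(km > 0), hill > 0,
            length(basal) == m, all(basal >= 0),
            length(degradation) == m, all(degradation > 0),
            sigma_noise >= 0, dt > 0, n_steps_per_q >= 1L, n_replicates >= 3L)
  if (dt * max(degradation) > 0.1) {
    warning("dt looks large relative to the fastest degradation rate; ",
            "the Euler-Maruyama step may be unstable")
  }
  structure(list(network = network, edge_sign = edge_sign, vmax = vmax,
                 km = km, hill = hill, basal = basal,
                 degradation = degradation, q_grid = q_grid,
                 sigma_noise = sigma_noise, dt = dt,
                 n_steps_per_q = as.integer(n_steps_per_q),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sde_config")
}

#' Default 16-node bifurcating circuit
#'
#' A packaged synthetic 16-node signed regulatory circuit used as the
#' standard simulator benchmark. Genes g01 and g02 form a mutually
#' activating pair whose basal rate is tuned to a saddle-node tangency at
#' q = 0: for q < 0 the pair rests on a low stable branch whose restoring
#' rate shrinks like sqrt(-q), and at q > 0 the low branch vanishes and the
#' system jumps to a high-expression state. The remaining 14 genes form a
#' downstream cascade of activating and inhibiting interactions. Rate
#' constants are the fixture's own documented choices.
#'
#' @return A list with the components [sde_config()] needs: `network`,
#'   `edge_sign`, `vmax`, `km`, `basal`, `degradation`.
#' @export
default_sde_network <- function() {
  genes <- sprintf("g%02d", 1:16)
  ed <- rbind(
    c(1, 2, +1), c(2, 1, +1),                       # bistable driver pair
    c(1, 3, +1), c(2, 4, +1), c(1, 5, +1), c(2, 6, +1),
    c(3, 7, +1), c(3, 8, -1), c(4, 9, +1), c(4, 10, -1),
    c(5, 11, +1), c(6, 12, +1),
    c(7, 13, +1), c(9, 14, +1), c(11, 15, -1), c(12, 16, +1),
    c(5, 9, +1), c(6, 10, +1), c(3, 10, +1), c(8, 13, +1))
  net <- directed_network(genes, cbind(genes[ed[, 1]], genes[ed[, 2]]),
                          require_acyclic = FALSE)
  # re-derive per-edge rows in the network's canonical edge order
  key_in <- paste(genes[ed[, 1]], genes[ed[, 2]])
  key_net <- paste(net$edges[, 1], net$edges[, 2])
  ord <- match(key_net, key_in)
  sign <- ed[ord, 3]
  driver <- key_net %in% c("g01 g02", "g02 g01")
  # driver pair: V = 2*K*d with K = 90 puts the saddle-node exactly at q = 0
  # once the basal rate is set to the tangency value below
  vmax <- ifelse(driver, 180, 10)
  km <- ifelse(driver, 90, 15)
  basal <- rep(2, 16)
  # tangency basal rate for the symmetric driver manifold:
  # solve g'(x*) = d at x* and set b = d*x* - V*x*^2/(K^2+x*^2)
  xstar <- .driver_tangency_x(V = 180, K = 90, d = 1)
  basal[1:2] <- xstar - 180 * xstar^2 / (90^2 + xstar^2)
  list(network = net, edge_sign = sign, vmax = vmax, km = km,
       basal = basal, degradation = rep(1, 16))
}

# x at which the driver activation slope equals the degradation rate
# (the smaller root; uniroot on V*2*K^2*x/(K^2+x^2)^2 - d)
.driver_tangency_x <- function(V, K, d) {
  f <- function(x) V * 2 * K^2 * x / (K^2 + x^2)^2 - d
  stats::uniroot(f, lower = 1e-6, upper = K / sqrt(3), tol = 1e-12)$root
}

#' Simulate the Michaelis-Menten SDE across a control-parameter sweep
#'
#' Euler-Maruyama integration of
#' `dx_i = [basal_i + sum_j MM(x_j) + q - degradation_i * x_i] dt + sigma dW`
#' with states reflected at 0 (abundances stay non-negative). For each q in
#' the grid, `n_replicates` independent trajectories are integrated for
#' `n_steps_per_q` steps from the low steady state and their endpoint
#' states become that stage's sample columns.
#'
#' @param config An [sde_config()].
#' @return List with `data` (a [staged_dataset()], one stage per q, labels
#'   `"q=<value>"`) and `gold` (the generating `directed_network`).
#' @export
simulate_mm_sde <- function(config) {
  stopifnot(inherits(config, "sde_config"))
  genes <- config$network$gene_ids
  m <- length(genes)
  from <- match(config$network$edges[, 1L], genes)
  to <- match(config$network$edges[, 2L], genes)
  h <- config$hill
  dt <- config$dt
  sdt <- sqrt(dt)
  nrep <- config$n_replicates
  x0 <- config$basal / config$degradation
  blocks <- vector("list", length(config$q_grid))
  for (qi in seq_along(config$q_grid)) {
    q <- config$q_grid[qi]
    if (config$sigma_noise > 0) set.seed(.derive_seed(config$seed, qi))
    x <- matrix(rep(x0, nrep), nrow = m)          # m x replicates
    for (step in seq_len(config$n_steps_per_q)) {
      drift <- matrix(config$basal + q, nrow = m, ncol = nrep) -
        config$degradation * x
      for (e in seq_along(from)) {
        xs <- x[from[e], ]
        xh <- xs^h
        kh <- config$km[e]^h
        term <- if (config$edge_sign[e] > 0) {
          config$vmax[e] * xh / (kh + xh)
        } else {
          config$vmax[e] * kh / (kh + xh)
        }
        drift[to[e], ] <- drift[to[e], ] + term
      }
      x <- x + drift * dt
      if (config$sigma_noise > 0) {
        x <- x + config$sigma_noise * sdt * matrix(stats::rnorm(m * nrep), nrow = m)
      }
      x <- abs(x)                                  # reflect at 0
      if (!all(is.finite(x))) {
        stop("non-finite state at q = ", q, ", step ", step,
             "; reduce dt or the noise strength")
      }
    }
    dimnames(x) <- list(genes, sprintf("q%d_rep%03d", qi, seq_len(nrep)))
    blocks[[qi]] <- expression_matrix(x)
  }
  labels <- sprintf("q=%+.3f", config$q_grid)
  names(blocks) <- labels
  list(data = staged_dataset(blocks, labels), gold = config$network)
}

#' Configuration for the planted-transition generator
#'
#' Defines a stage-wise dataset in which one designated critical stage
#' carries the two early-warning features within a core subnetwork:
#' noise variance inflated by `variance_inflation`, and a shared latent
#' factor sized so that the expected pairwise correlation between any two
#' core genes is at least `correlation_boost`.
#'
#' @param m_genes Total genes (default 20).
#' @param n_samples_per_stage Samples per stage (default 50).
#' @param n_stages Number of ordered stages (default 6).
#' @param critical_stage Index of the planted critical stage (default 4);
#'   must lie in \[3, n_stages\] so the stage is testable.
#' @param core_genes Character vector of core genes (default: the first 8).
#' @param core_edges Two-column matrix of true directed edges within the
#'   core (default: a 7-edge regulatory tree over the 8 core genes).
#' @param beta Regulatory coefficient on each true edge (default 0.8).
#' @param baseline_sd Baseline noise standard deviation, shared by root and
#'   child noise terms (default 1).
#' @param variance_inflation Factor (> 1) multiplying noise variances at the
#'   critical stage (default 4).
#' @param correlation_boost Target minimum expected pairwise correlation
#'   among core genes at the critical stage, in \[0, 1) (default 0.6).
#' @param seed Integer seed.
#' @return A list of class `"planted_config"`.
#' @export
planted_config <- function(m_genes = 20L, n_samples_per_stage = 50L,
                           n_stages = 6L, critical_stage = 4L,
                           core_genes = NULL, core_edges = NULL,
                           beta = 0.8, baseline_sd = 1,
                           variance_inflation = 4, correlation_boost = 0.6,
                           seed = 1L) {
  genes <- sprintf("g%02d", seq_len(m_genes))
  if (is.null(core_genes)) core_genes <- genes[seq_len(min(8L, m_genes))]
  if (is.null(core_edges)) {
    cg <- core_genes
    core_edges <- cbind(cg[c(1, 1, 2, 2, 3, 3, 4)], cg[c(2, 3, 4, 5, 6, 7, 8)])
    core_edges <- core_edges[core_edges[, 1] != core_edges[, 2] &
                               !is.na(core_edges[, 2]), , drop = FALSE]
  }
  stopifnot(m_genes >= length(core_genes), length(core_genes) >= 1L,
            n_stages >= 3L, critical_stage >= 3L, critical_stage <= n_stages,
            n_samples_per_stage >= 3L, variance_inflation >= 1,
            correlation_boost >= 0, correlation_boost < 1, baseline_sd > 0)
  structure(list(m_genes = as.integer(m_genes),
                 n_samples_per_stage = as.integer(n_samples_per_stage),
                 n_stages = as.integer(n_stages),
                 critical_stage = as.integer(critical_stage),
                 gene_ids = genes, core_genes = core_genes,
                 core_edges = core_edges, beta = beta,
                 baseline_sd = baseline_sd,
                 variance_inflation = variance_inflation,
                 correlation_boost = correlation_boost,
                 seed = as.integer(seed)),
            class = "planted_config")
}

#' Generate a stage-wise dataset with a planted critical transition
#'
#' Off-transition stages draw the core genes from the linear structural
#' equation model over the true edge list: roots are Gaussian noise with sd
#' `baseline_sd` and each child is `beta * parent` plus noise with the same
#' sd, so variance accumulates along regulatory depth. The unequal
#' variances make edge orientations identifiable by the network score,
#' which is what lets the pre-transition search land on a stable structure.
#' At the critical stage every noise term's variance is multiplied by
#' `variance_inflation` and a shared standard normal latent factor is added
#' to each core gene `i` with loading `sqrt(c * v_i)` where
#' `c = boost / (1 - boost) * variance_inflation` and `v_i` is the gene's
#' off-transition variance; this makes the expected correlation of every
#' unrelated core pair exactly `correlation_boost` (regulatorily related
#' pairs higher). Background genes are independent noise throughout.
#'
#' @param config A [planted_config()].
#' @return List with `data` (a [staged_dataset()], stages `"S1"`, ...),
#'   `gold` (the true core `directed_network` over the full gene universe)
#'   and `critical_stage` (the planted stage label).
#' @export
generate_planted_transition <- function(config) {
  stopifnot(inherits(config, "planted_config"))
  genes <- config$gene_ids
  core <- config$core_genes
  bg <- setdiff(genes, core)
  n <- config$n_samples_per_stage
  gold <- directed_network(genes, config$core_edges)
  parent_of <- stats::setNames(rep(NA_character_, length(core)), core)
  for (k in seq_len(nrow(config$core_edges))) {
    parent_of[config$core_edges[k, 2L]] <- config$core_edges[k, 1L]
  }
  topo <- .topo_sort_tree(core, parent_of)
  # theoretical off-transition variance of each core gene (noise sd is the
  # same for roots and children, so variance grows along regulatory depth)
  v <- stats::setNames(rep(config$baseline_sd^2, length(core)), core)
  for (g in topo) {
    p <- parent_of[[g]]
    if (!is.na(p)) v[g] <- config$beta^2 * v[p] + config$baseline_sd^2
  }
  blocks <- vector("list", config$n_stages)
  for (st in seq_len(config$n_stages)) {
    set.seed(.derive_seed(config$seed, 13L, st))
    crit <- st == config$critical_stage
    noise_scale <- if (crit) sqrt(config$variance_inflation) else 1
    x <- matrix(0, length(genes), n, dimnames = list(genes, NULL))
    for (g in topo) {
      p <- parent_of[[g]]
      base <- if (is.na(p)) 0 else config$beta * x[p, ]
      x[g, ] <- base + stats::rnorm(n, sd = config$baseline_sd * noise_scale)
    }
    if (crit && config$correlation_boost > 0) {
      cc <- config$correlation_boost / (1 - config$correlation_boost) *
        config$variance_inflation
      z <- stats::rnorm(n)
      x[core, ] <- x[core, , drop = FALSE] + sqrt(cc * v[core]) %o% z
    }
    if (length(bg) > 0L) {
      x[bg, ] <- matrix(stats::rnorm(length(bg) * n, sd = config$baseline_sd),
                        length(bg), n)
    }
    colnames(x) <- sprintf("S%d_s%03d", st, seq_len(n))
    blocks[[st]] <- expression_matrix(x)
  }
  labels <- sprintf("S%d", seq_len(config$n_stages))
  names(blocks) <- labels
  list(data = staged_dataset(blocks, labels), gold = gold,
       critical_stage = labels[config$critical_stage])
}

# topological order of a forest given a single-parent map (roots first)
.topo_sort_tree <- function(nodes, parent_of) {
  depth <- function(g) {
    d <- 0L
    while (!is.na(parent_of[[g]])) {
      g <- parent_of[[g]]
      d <- d + 1L
      if (d > length(nodes)) stop("core edge list contains a cycle")
    }
    d
  }
  nodes[order(vapply(nodes, depth, integer(1)))]
}
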