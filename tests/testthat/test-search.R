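test_that("random initial DAGs conform to the skeleton and are seed-deterministic", {
  genes <- c("a", "b", "c")
  empty <- undirected_network(genes, NULL)
  expect_equal(nrow(random_initial_dag(empty, seed = 1)$edges), 0L)

  full <- undirected_network(genes, rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  dag <- random_initial_dag(full, init_edge_prob = 1, seed = 3)
  expect_equal(nrow(dag$edges), 3L)
  expect_true(igraph_is_dag(dag))

  expect_identical(random_initial_dag(full, seed = 9)$edges,
                   random_initial_dag(full, seed = 9)$edges)
  # different seeds on a 10-node complete skeleton diversify
  g10 <- sprintf("n%02d", 1:10)
  pairs <- t(combn(g10, 2))
  big <- undirected_network(g10, pairs)
  d1 <- random_initial_dag(big, seed = 1)
  d2 <- random_initial_dag(big, seed = 2)
  expect_false(identical(d1$edges, d2$edges))
  # skeleton containment
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(key(d1$edges) %in% key(pairs)))
})

test_that("move enumeration matches hand-enumerated cases and respects acyclicity", {
  # single skeleton edge already oriented: nothing to add, one delete, one reverse
  cbn <- undirected_network(c("a", "b"), rbind(c("a", "b")))
  dag <- directed_network(c("a", "b"), rbind(c("a", "b")))
  mv <- enumerate_moves(dag, cbn)
  expect_equal(nrow(mv$add), 0L)
  expect_equal(mv$delete, data.frame(from = "a", to = "b"))
  expect_equal(mv$reverse, data.frame(from = "a", to = "b"))

  # chain a->b->c with a complete skeleton: a->c is addable, c->a closes a cycle
  cbn3 <- undirected_network(c("a", "b", "c"),
                             rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  chain <- directed_network(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  mv3 <- enumerate_moves(chain, cbn3)
  addkey <- paste(mv3$add$from, mv3$add$to)
  expect_true("a c" %in% addkey)
  expect_false("c a" %in% addkey)

  # empty everything
  mv0 <- enumerate_moves(directed_network("a", NULL, require_acyclic = TRUE),
                         undirected_network("a", NULL))
  expect_equal(vapply(mv0, nrow, integer(1)), c(add = 0L, delete = 0L, reverse = 0L))
})

test_that("every enumerated move keeps the state a DAG inside the skeleton", {
  set.seed(10)
  for (rep in 1:5) {
    x <- rand_expr(5L, 12L)
    cbn <- build_cbn(x, mi_params(threshold_T = 0.01))
    dag <- random_initial_dag(cbn, 0.5, seed = rep)
    mv <- enumerate_moves(dag, cbn)
    skel <- paste(cbn$edges[, 1], cbn$edges[, 2])
    for (kind in names(mv)) {
      tab <- mv[[kind]]
      for (k in seq_len(nrow(tab))) {
        nd <- apply_move(dag, kind, tab$from[k], tab$to[k])
        expect_true(igraph_is_dag(nd))
        if (nrow(nd$edges) > 0L) {
          ekey <- paste(pmin(nd$edges[, 1], nd$edges[, 2]),
                        pmax(nd$edges[, 1], nd$edges[, 2]))
          expect_true(all(ekey %in% skel))
        }
      }
    }
  }
})

test_that("hill climbing finds the single informative edge in a 2-gene system", {
  set.seed(20)
  g1 <- rnorm(50)
  g2 <- 1.5 * g1 + rnorm(50, sd = 0.3)
  x <- expression_matrix(rbind(g1 = g1, g2 = g2))
  cbn <- undirected_network(c("g1", "g2"), rbind(c("g1", "g2")))
  empty <- directed_network(c("g1", "g2"), NULL)
  res <- hill_climb(empty, cbn, x)
  expect_equal(nrow(res$network$edges), 1L)
  # the climber reaches the argmin over the three candidate structures
  h_empty <- h_score(empty, x)$h_score
  h_fwd <- h_score(directed_network(c("g1", "g2"), rbind(c("g1", "g2"))), x)$h_score
  h_bwd <- h_score(directed_network(c("g1", "g2"), rbind(c("g2", "g1"))), x)$h_score
  expect_equal(res$h_score, min(h_empty, h_fwd, h_bwd), tolerance = 1e-12)
  expect_lt(res$h_score, h_empty)

  # an already-optimal start is a fixed point
  res2 <- hill_climb(res$network, cbn, x)
  expect_equal(res2$network$edges, res$network$edges)
  expect_equal(length(attr(res2, "trajectory")), 1L)
})

test_that("the H trajectory is non-increasing along every climb", {
  set.seed(21)
  for (rep in 1:5) {
    x <- rand_expr(5L, 15L)
    cbn <- build_cbn(x, mi_params(threshold_T = 0.01))
    init <- random_initial_dag(cbn, 0.7, seed = rep)
    res <- hill_climb(init, cbn, x)
    traj <- attr(res, "trajectory")
    expect_true(all(diff(traj) < 0))
    expect_lte(res$h_score, h_score(init, x)$h_score)
    # final H from incremental bookkeeping equals a full rescore
    expect_equal(res$h_score, h_score(res$network, x)$h_score, tolerance = 1e-9)
  }
})

test_that("restart climbs on 3-gene chain data reach the exhaustive minimum", {
  set.seed(22)
  g1 <- rnorm(100)
  g2 <- 1.2 * g1 + rnorm(100, sd = 0.4)
  g3 <- 0.9 * g2 + rnorm(100, sd = 0.4)
  x <- expression_matrix(rbind(g1 = g1, g2 = g2, g3 = g3))
  cbn <- build_cbn(x)
  best_oracle <- oracle_exhaustive_min_h(cbn, x)
  for (seed in 1:5) {
    init <- random_initial_dag(cbn, 0.5, seed = seed)
    res <- hill_climb(init, cbn, x)
    expect_equal(res$h_score, best_oracle, tolerance = 1e-9)
  }
})

test_that("infer_global_optimum returns the best restart, reproducibly", {
  set.seed(23)
  x <- rand_expr(4L, 30L)
  sp <- search_params(n_restarts_I = 5L, seed = 99L)
  fit <- infer_global_optimum(x, search_params = sp)
  expect_equal(length(fit$restart_scores), 5L)
  expect_equal(fit$h_score, min(fit$restart_scores))
  expect_true(igraph_is_dag(fit$network))
  # bit-identical reproducibility from (data, params, seed)
  fit2 <- infer_global_optimum(x, search_params = sp)
  expect_identical(fit2$network$edges, fit$network$edges)
  expect_identical(fit2$h_score, fit$h_score)
  expect_identical(fit2$restart_scores, fit$restart_scores)
  # a single restart is one hill climb from the derived seed
  sp1 <- search_params(n_restarts_I = 1L, seed = 7L)
  one <- infer_global_optimum(x, search_params = sp1)
  cbn <- build_cbn(x)
  init <- random_initial_dag(cbn, 0.5, seed = bcti:::.derive_seed(7L, 1L))
  expect_equal(one$h_score, hill_climb(init, cbn, x)$h_score)
})

test_that("a 4-gene linear system is solved to the exhaustive optimum", {
  set.seed(24)
  g1 <- rnorm(60)
  g2 <- 1.1 * g1 + rnorm(60, sd = 0.5)
  g3 <- -0.9 * g1 + rnorm(60, sd = 0.5)
  g4 <- 0.8 * g2 + 0.7 * g3 + rnorm(60, sd = 0.5)
  x <- expression_matrix(rbind(g1 = g1, g2 = g2, g3 = g3, g4 = g4))
  cbn <- build_cbn(x)
  fit <- infer_global_optimum(x, search_params = search_params(20L, seed = 5L))
  expect_equal(fit$h_score, oracle_exhaustive_min_h(cbn, x), tolerance = 1e-9)
})
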