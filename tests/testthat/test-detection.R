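test_that("the score t-test matches stats::t.test and handles degenerate histories", {
  expect_equal(ttest_pvalue(c(1, 1, 1, 1), 1), 1)
  expect_equal(ttest_pvalue(c(1, 1, 1, 1), 2), 0)
  expect_equal(ttest_pvalue(c(0, 2), 1), 1)

  hist <- c(1.0, 1.1, 0.9, 1.0)
  # hand-derived: t = (1.0 - 5.0) / (sd/sqrt(4)), sd ~ 0.08165 -> |t| ~ 97.98
  tstat <- (mean(hist) - 5.0) / (sd(hist) / 2)
  expect_equal(tstat, -97.97958971, tolerance = 1e-8)
  expect_equal(ttest_pvalue(hist, 5.0),
               t.test(hist, mu = 5.0)$p.value, tolerance = 1e-12)
  expect_lt(ttest_pvalue(hist, 5.0), 1e-3)
  # one-sided variant agrees with the independent implementation
  expect_equal(ttest_pvalue(hist, 5.0, sided = "greater"),
               t.test(hist, mu = 5.0, alternative = "less")$p.value,
               tolerance = 1e-12)
  expect_error(ttest_pvalue(1, 2), "at least 2")
})

test_that("p-values are invariant to affine transforms of the whole series", {
  hist <- c(10, 11, 9.5, 10.2)
  cur <- 14
  p1 <- ttest_pvalue(hist, cur)
  p2 <- ttest_pvalue(3 * hist - 7, 3 * cur - 7)
  expect_equal(p1, p2, tolerance = 1e-12)
})

# assemble a bcti_series by hand from a score vector
series_from_scores <- function(scores, consistency = NULL) {
  tmax <- length(scores)
  pv <- rep(NA_real_, tmax)
  for (t in 3:tmax) pv[t] <- ttest_pvalue(scores[seq_len(t - 1)], scores[t])
  structure(list(stage_labels = sprintf("S%d", seq_len(tmax)),
                 scores_S = scores, p_values = pv,
                 restart_consistency = consistency,
                 tpr = rep(NA_real_, tmax), networks = NULL),
            class = "bcti_series")
}

test_that("detect_critical_state calls the planted jump and nothing on flat series", {
  flat <- series_from_scores(c(1.00, 1.01, 0.99, 1.02, 1.00))
  expect_true(is.na(detect_critical_state(flat)$critical_stage))

  jump <- series_from_scores(c(1.00, 1.02, 0.98, 1.01, 3.0, 1.0))
  det <- detect_critical_state(jump)
  expect_equal(det$critical_stage, "S5")
  expect_equal(det$critical_index, 5L)

  # degenerate alpha = 1: the first testable stage is always returned
  lax <- detect_critical_state(flat, detection_params(alpha = 0.999999))
  expect_equal(lax$critical_index, 3L)
})

test_that("instability metrics behave at their boundary cases", {
  genes <- c("a", "b", "c")
  ref <- directed_network(genes, rbind(c("a", "b"), c("b", "c")))
  expect_equal(structural_instability(ref, ref, genes), 1)
  expect_error(structural_instability(ref, directed_network(genes, NULL), genes),
               "nonempty")

  n1 <- directed_network(genes, rbind(c("a", "b")))
  n2 <- directed_network(genes, rbind(c("b", "c")))
  expect_equal(restart_consistency(list(n1, n1, n1)), 1)
  expect_equal(restart_consistency(list(n1, n2)), 0)
  e <- directed_network(genes, NULL)
  expect_equal(restart_consistency(list(e, e)), 1)  # identical empties agree
  expect_error(restart_consistency(list(n1)), "at least 2")
})

test_that("identical stage blocks give identical scores and networks", {
  set.seed(30)
  g1 <- rnorm(40)
  g2 <- 1.4 * g1 + rnorm(40, sd = 0.3)
  g3 <- rnorm(40)
  x <- expression_matrix(rbind(g1 = g1, g2 = g2, g3 = g3))
  ds <- staged_dataset(list(A = x, B = x, C = x), c("A", "B", "C"))
  ser <- compute_bcti_series(ds, search_params = search_params(10L, seed = 2L))
  expect_equal(ser$scores_S[2], ser$scores_S[1], tolerance = 1e-12)
  expect_equal(ser$scores_S[3], ser$scores_S[1], tolerance = 1e-12)
  expect_identical(ser$networks[[2]]$network$edges, ser$networks[[1]]$network$edges)
  # equal history and current score: degenerate p = 1, no call
  expect_equal(ser$p_values[3], 1)
  expect_true(is.na(detect_critical_state(ser)$critical_stage))
})

test_that("a doubled-noise stage raises the score of a gene-pair system", {
  set.seed(31)
  g1a <- rnorm(60); g2a <- g1a + rnorm(60, sd = 0.5)
  g1b <- rnorm(60, sd = 2); g2b <- g1b + rnorm(60, sd = 1)
  a <- expression_matrix(rbind(g1 = g1a, g2 = g2a))
  b <- expression_matrix(rbind(g1 = g1b, g2 = g2b))
  ds <- staged_dataset(list(S1 = a, S2 = b), c("S1", "S2"))
  ser <- compute_bcti_series(ds, search_params = search_params(5L, seed = 3L))
  expect_gt(ser$scores_S[2], ser$scores_S[1])
})

test_that("the planted transition is detected end-to-end with corroboration", {
  sim <- generate_planted_transition(planted_config(seed = 11L))
  ser <- compute_bcti_series(sim$data, search_params = search_params(seed = 11L),
                             reference = sim$gold)
  det <- detect_critical_state(ser)
  expect_equal(det$critical_stage, sim$critical_stage)
  expect_lt(det$p_values[det$critical_index], 0.05)
  # the score at the planted stage exceeds the pre-transition mean
  expect_gt(ser$scores_S[4], mean(ser$scores_S[1:3]))
})

test_that("equalize_n subsamples every stage to the minimum size", {
  set.seed(32)
  blocks <- list(
    A = expression_matrix(matrix(rnorm(3 * 6), 3, 6,
                                 dimnames = list(c("a", "b", "c"), NULL))),
    B = expression_matrix(matrix(rnorm(3 * 4), 3, 4,
                                 dimnames = list(c("a", "b", "c"), NULL))))
  ds <- staged_dataset(blocks, c("A", "B"))
  ser <- compute_bcti_series(ds, search_params = search_params(2L, seed = 1L),
                             equalize_n = TRUE)
  expect_length(ser$scores_S, 2L)
  # raw scores scale with n; equalized runs remove the size confound, so the
  # block-A score must come from a 4-sample fit (bounded by the 4-sample SS)
  ser_raw <- compute_bcti_series(ds, search_params = search_params(2L, seed = 1L))
  expect_false(isTRUE(all.equal(ser$scores_S[1], ser_raw$scores_S[1])))
})
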