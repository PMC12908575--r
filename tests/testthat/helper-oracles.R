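# Fixture builders and independent oracles used across the suite.

# small random expression matrix (seeded by the caller)
rand_expr <- function(m = 4L, n = 20L, genes = sprintf("g%d", seq_len(m))) {
  expression_matrix(matrix(rnorm(m * n), m, n, dimnames = list(genes, NULL)))
}

# a pair of vectors with an exact sample Pearson correlation rho:
# built from two orthonormal centered vectors
vectors_with_cor <- function(rho, n = 12L) {
  u <- rep(c(1, -1), length.out = n)
  v <- rep(c(1, 1, -1, -1), length.out = n)
  v <- v - mean(v)
  v <- v - u * sum(u * v) / sum(u * u)
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  list(x = u, y = rho * u + sqrt(1 - rho^2) * v)
}

# independent acyclicity oracle
igraph_is_dag <- function(net) {
  if (nrow(net$edges) == 0L) return(TRUE)
  g <- igraph::graph_from_edgelist(net$edges, directed = TRUE)
  igraph::is_dag(g)
}

# independent scorer: per-node residual sum of squares via base lm.fit on
# centered data, plus the penalty formula (no shared code with h_score)
oracle_h <- function(edges, expr, lambda = 1) {
  x <- unclass(expr)
  x <- x - rowMeans(x)
  n <- ncol(x)
  genes <- rownames(x)
  total <- 0
  for (g in genes) {
    pa <- if (length(edges) == 0L || nrow(edges) == 0L) character(0) else
      edges[edges[, 2L] == g, 1L]
    if (length(pa) == 0L) {
      rss <- sum(x[g, ]^2)
    } else {
      X <- t(x[pa, , drop = FALSE])
      fit <- lm.fit(X, x[g, ])
      rss <- sum(fit$residuals^2)
    }
    total <- total + rss + lambda * length(pa) * log(n)
  }
  total
}

# exhaustive-enumeration oracle: minimum H over every DAG whose skeleton is
# a subset of the CBN (each skeleton pair absent / oriented one way / the
# other), acyclicity checked with igraph
oracle_exhaustive_min_h <- function(cbn, expr, lambda = 1) {
  ne <- nrow(cbn$edges)
  if (ne == 0L) return(oracle_h(NULL, expr, lambda))
  best <- Inf
  choice <- rep(0L, ne)
  repeat {
    sel <- choice > 0L
    edges <- NULL
    if (any(sel)) {
      e <- cbn$edges[sel, , drop = FALSE]
      flip <- choice[sel] == 2L
      e[flip, ] <- e[flip, c(2L, 1L), drop = FALSE]
      edges <- e
    }
    ok <- is.null(edges) ||
      igraph::is_dag(igraph::graph_from_edgelist(edges, directed = TRUE))
    if (ok) best <- min(best, oracle_h(edges, expr, lambda))
    # increment base-3 counter
    i <- 1L
    while (i <= ne) {
      choice[i] <- choice[i] + 1L
      if (choice[i] <= 2L) break
      choice[i] <- 0L
      i <- i + 1L
    }
    if (i > ne) break
  }
  best
}

# a quick staged dataset with two identical blocks
two_stage_dataset <- function(expr) {
  staged_dataset(list(A = expr, B = expr), c("A", "B"))
}

# Confusion-count fixture: stage-wise TP/FP/FN/TN/TPR rows of the published
# pathway-recovery benchmark (15-gene COAD/LUAD universes, 30-gene THCA).
table1_rows <- function() {
  rows <- rbind(
    c("COAD", "I",    6, 14,  9, 181, 0.4000, 15),
    c("COAD", "IIA",  4, 23, 11, 172, 0.2667, 15),
    c("COAD", "IIB",  2, 19, 13, 176, 0.1333, 15),
    c("COAD", "III",  7, 19,  8, 176, 0.4667, 15),
    c("COAD", "IV",   2, 23, 13, 172, 0.1333, 15),
    c("LUAD", "I",    5, 23,  7, 175, 0.4167, 15),
    c("LUAD", "IIA",  2, 14, 10, 184, 0.1667, 15),
    c("LUAD", "IIB",  3, 16,  9, 182, 0.2500, 15),
    c("LUAD", "IIIA", 2, 13, 10, 185, 0.1667, 15),
    c("LUAD", "IIIB", 0, 11, 12, 187, 0.0000, 15),
    c("LUAD", "IV",   1, 15, 11, 183, 0.0833, 15),
    c("THCA", "I",    9, 59, 15, 787, 0.3750, 30),
    c("THCA", "II",   3, 43, 21, 803, 0.1250, 30),
    c("THCA", "III",  4, 54, 20, 792, 0.1667, 30),
    c("THCA", "IV",   4, 38, 20, 808, 0.1667, 30))
  data.frame(cancer = rows[, 1], stage = rows[, 2],
             tp = as.integer(rows[, 3]), fp = as.integer(rows[, 4]),
             fn = as.integer(rows[, 5]), tn = as.integer(rows[, 6]),
             tpr = as.numeric(rows[, 7]), m = as.integer(rows[, 8]),
             stringsAsFactors = FALSE)
}

# build a (predicted, gold) network pair over m genes realizing given
# tp/fp/fn counts
networks_with_counts <- function(tp, fp, fn, m) {
  genes <- sprintf("t%02d", seq_len(m))
  pairs <- expand.grid(from = genes, to = genes, stringsAsFactors = FALSE)
  pairs <- as.matrix(pairs[pairs$from != pairs$to, ])
  stopifnot(tp + fp + fn <= nrow(pairs))
  gold <- pairs[seq_len(tp + fn), , drop = FALSE]
  pred <- rbind(pairs[seq_len(tp), , drop = FALSE],
                pairs[tp + fn + seq_len(fp), , drop = FALSE])
  list(predicted = directed_network(genes, pred, require_acyclic = FALSE),
       gold = directed_network(genes, gold, require_acyclic = FALSE),
       genes = genes)
}
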