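# Per-node structural-equation-model fit and the MDL-style network score.
# Each node is modelled as an intercept-free linear combination of its
# parents plus Gaussian noise; the local score is the residual sum of
# squares F plus a complexity penalty lambda * |parents| * log(n). The
# network score H is the sum of local scores, which makes it decomposable:
# a single-edge move only rescores the nodes whose parent set changed.
#
# The least-squares solve is minimum-norm via the singular value
# decomposition, with no ridge term: near-collinear parent sets (the
# multicollinearity that appears when genes co-vary strongly near a critical
# transition) are allowed to destabilize the coefficient estimates, because
# that instability is part of the detection signal. The residual itself
# stays well-defined.

#' Scoring parameters
#'
#' @param lambda_reg Non-negative complexity weight (default `1.0`; the
#'   penalty then reduces to the familiar BIC-like `|parents| * log(n)`).
#' @param center_genes Mean-center each gene's row within the stage before
#'   scoring (default `TRUE`). The model has no intercept, so centering is
#'   required for sensible fits; rows are deliberately not scaled to unit
#'   variance because the score's early-warning behaviour rests on the
#'   variance signal.
#' @return A list of class `"score_params"`.
#' @export
score_params <- function(lambda_reg = 1.0, center_genes = TRUE) {
  stopifnot(is.numeric(lambda_reg), length(lambda_reg) == 1L, lambda_reg >= 0,
            is.logical(center_genes), length(center_genes) == 1L)
  structure(list(lambda_reg = lambda_reg, center_genes = center_genes),
            class = "score_params")
}

#' Fit the structural equation of one node
#'
#' Minimum-norm least squares of `child` on the rows of `parents` (no
#' intercept). With an empty parent set the fit is the zero prediction and
#' the residual sum of squares is `sum(child^2)`. Rank-deficient designs
#' (duplicated or collinear parents, or more parents than samples) get the
#' pseudoinverse solution of minimal Euclidean norm.
#'
#' @param child Numeric vector of length n.
#' @param parents Numeric p x n matrix (rows = parent genes); `NULL` or a
#'   0-row matrix means no parents.
#' @return List of class `"sem_fit"` with `theta_hat` (length-p coefficient
#'   vector) and `rss` (residual sum of squares, the goodness-of-fit term F).
#' @export
fit_sem <- function(child, parents = NULL) {
  child <- as.numeric(child)
  n <- length(child)
  if (is.null(parents) || NROW(parents) == 0L) {
    return(structure(list(theta_hat = numeric(0), rss = sum(child^2)),
                     class = "sem_fit"))
  }
  parents <- matrix(as.numeric(parents), nrow = NROW(parents))
  if (ncol(parents) != n) {
    stop("dimension mismatch: child has ", n, " samples, parents have ",
         ncol(parents))
  }
  X <- t(parents)                      # n x p design
  sv <- svd(X)
  pos <- sv$d > max(sv$d[1L], 0) * 1e-12
  dinv <- ifelse(pos, 1 / sv$d, 0)
  theta <- sv$v %*% (dinv * crossprod(sv$u, child))
  resid <- child - X %*% theta
  structure(list(theta_hat = as.numeric(theta),
                 rss = max(0, sum(resid^2))),
            class = "sem_fit")
}

# rss only, on a pre-centered genes x samples matrix; used by the search hot
# path (the coefficient vector itself is not needed to score a move)
.rss <- function(x, child_idx, parent_idx) {
  y <- x[child_idx, ]
  if (length(parent_idx) == 0L) return(sum(y^2))
  fit_sem(y, x[parent_idx, , drop = FALSE])$rss
}

.center_rows <- function(x) x - rowMeans(x)

#' Local subnetwork score of one node
#'
#' `F + lambda * |parents| * log(n)` where F is the residual sum of squares
#' of the node's structural-equation fit on (optionally centered) data and
#' the penalty counts one parameter per parent. Natural log.
#'
#' @param child_gene Gene id of the node being scored.
#' @param parent_set Character vector of parent gene ids (must not contain
#'   the child).
#' @param expr An expression matrix containing all involved genes.
#' @param params A [score_params()] object.
#' @return The local score (numeric scalar).
#' @export
local_score <- function(child_gene, parent_set, expr, params = score_params()) {
  if (child_gene %in% parent_set) stop("parent set must not contain the child")
  x <- unclass(expr)
  if (params$center_genes) x <- .center_rows(x)
  ci <- match(child_gene, rownames(x))
  pi <- match(parent_set, rownames(x))
  if (anyNA(c(ci, pi))) stop("gene(s) absent from the expression matrix")
  n <- ncol(x)
  .rss(x, ci, pi) + params$lambda_reg * length(pi) * log(n)
}

#' Score a directed acyclic network
#'
#' Total network score H = sum over nodes of the local subnetwork scores.
#' A pure function of (network, data, parameters).
#'
#' @param dag A `directed_network` (must be acyclic) over the genes of
#'   `expr`.
#' @param expr An expression matrix.
#' @param params A [score_params()] object.
#' @return A [scored_network()] carrying `h_score` and the per-node
#'   `local_scores`.
#' @export
h_score <- function(dag, expr, params = score_params()) {
  if (!is_acyclic(dag)) stop("network must be acyclic to be scored")
  x <- unclass(expr)
  if (params$center_genes) x <- .center_rows(x)
  genes <- rownames(x)
  if (!setequal(dag$gene_ids, genes)) {
    stop("network genes must match the expression matrix genes")
  }
  n <- ncol(x)
  parents <- .parent_list(dag, genes)
  locals <- vapply(seq_along(genes), function(i) {
    .rss(x, i, parents[[i]]) + params$lambda_reg * length(parents[[i]]) * log(n)
  }, numeric(1))
  names(locals) <- genes
  scored_network(dag, sum(locals), locals)
}

# parent sets as integer indices into `genes`, one entry per gene
.parent_list <- function(dag, genes = dag$gene_ids) {
  pl <- rep(list(integer(0)), length(genes))
  if (nrow(dag$edges) > 0L) {
    to <- match(dag$edges[, 2L], genes)
    from <- match(dag$edges[, 1L], genes)
    for (k in seq_along(to)) pl[[to[k]]] <- c(pl[[to[k]]], from[k])
  }
  pl
}
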