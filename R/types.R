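#' Construct an expression matrix
#'
#' An expression matrix is a numeric genes-by-samples matrix with unique gene
#' identifiers as row names and unique sample identifiers as column names.
#' All downstream machinery (skeleton construction, scoring, search,
#' detection) consumes this container.
#'
#' @param values Numeric matrix, rows = genes, columns = samples.
#' @param gene_ids Character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `colnames(values)`, or `s1, s2, ...` when absent.
#' @return A numeric matrix of class `"expression_matrix"` with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) stop("gene_ids are required (row names missing)")
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(ncol(values)))
  rownames(values) <- as.character(gene_ids)
  colnames(values) <- as.character(sample_ids)
  class(values) <- c("expression_matrix", class(values))
  validate_expression_matrix(values)
}

#' Validate an expression matrix
#'
#' Checks the container invariants: at least 2 genes, at least 3 samples,
#' unique gene and sample identifiers, and no missing or non-finite values.
#'
#' @param x Matrix to validate.
#' @return `x`, invisibly unchanged, if valid; otherwise an error naming the
#'   offending gene, sample, or cell.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression matrix must be numeric")
  if (nrow(x) < 2L) stop("expression matrix needs at least 2 genes, got ", nrow(x))
  if (ncol(x) < 3L) stop("expression matrix needs at least 3 samples, got ", ncol(x))
  g <- rownames(x)
  if (anyDuplicated(g)) {
    stop("duplicated gene id(s): ", paste(unique(g[duplicated(g)]), collapse = ", "))
  }
  s <- colnames(x)
  if (anyDuplicated(s)) {
    stop("duplicated sample id(s): ", paste(unique(s[duplicated(s)]), collapse = ", "))
  }
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("missing/non-finite value at gene '", g[bad[1L, 1L]],
         "', sample '", s[bad[1L, 2L]], "'")
  }
  x
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x), " genes x ", ncol(x), " samples\n", sep = "")
  invisible(x)
}

#' Construct a staged dataset
#'
#' Bundles one expression matrix per ordered stage (the time axis of the
#' score trajectory). Every block must share the same genes in the same
#' order, and every stage must have at least 3 samples.
#'
#' @param blocks Named list of expression matrices, one per stage.
#' @param stage_labels Ordered character vector of stage labels; defaults to
#'   `names(blocks)`.
#' @return An object of class `"staged_dataset"` with fields `stage_labels`
#'   and `blocks`.
#' @export
staged_dataset <- function(blocks, stage_labels = names(blocks)) {
  stage_labels <- as.character(stage_labels)
  if (length(stage_labels) < 2L) stop("a staged dataset needs at least 2 stages")
  if (!setequal(stage_labels, names(blocks)) ||
      length(stage_labels) != length(blocks)) {
    stop("stage_labels must match the names of blocks exactly")
  }
  blocks <- blocks[stage_labels]
  ref_genes <- rownames(blocks[[1L]])
  for (st in stage_labels) {
    b <- blocks[[st]]
    validate_expression_matrix(unclass(b))
    if (!identical(rownames(b), ref_genes)) {
      stop("stage '", st, "' does not share the common gene order")
    }
    if (ncol(b) < 3L) stop("stage '", st, "' has fewer than 3 samples")
  }
  structure(list(stage_labels = stage_labels, blocks = blocks),
            class = "staged_dataset")
}

#' @export
print.staged_dataset <- function(x, ...) {
  ns <- vapply(x$blocks, ncol, integer(1))
  cat("<staged_dataset> ", nrow(x$blocks[[1L]]), " genes, ",
      length(x$stage_labels), " stages (",
      paste0(x$stage_labels, ":", ns, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# normalize an edge table to a 2-column character matrix
.edge_matrix <- function(edges) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L) ||
      length(edges) == 0L) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (!is.matrix(edges)) edges <- matrix(edges, ncol = 2L, byrow = TRUE)
  edges <- edges[, 1:2, drop = FALSE]
  storage.mode(edges) <- "character"
  colnames(edges) <- c("from", "to")
  edges
}

.check_edge_endpoints <- function(edges, gene_ids) {
  unknown <- setdiff(unique(c(edges)), gene_ids)
  if (length(unknown) > 0L) {
    stop("edge endpoint(s) not in gene universe: ",
         paste(unknown, collapse = ", "))
  }
  if (any(edges[, 1L] == edges[, 2L])) {
    bad <- edges[edges[, 1L] == edges[, 2L], 1L]
    stop("self-loop(s) not allowed: ", paste(unique(bad), collapse = ", "))
  }
  invisible(edges)
}

#' Construct an undirected network (correlation basis network)
#'
#' An undirected network over a gene universe; each edge is an unordered
#' gene pair. Used as the skeleton ("CBN") constraining the directed search.
#' Duplicate edges and both orientations of the same pair collapse to a
#' single canonical (lexicographically sorted) pair.
#'
#' @param gene_ids Character vector of the gene universe.
#' @param edges Two-column character matrix/data.frame of gene pairs (or a
#'   flat vector read row-wise); may be empty.
#' @return An object of class `"undirected_network"` with fields `gene_ids`
#'   and `edges` (2-column character matrix of sorted pairs).
#' @export
undirected_network <- function(gene_ids, edges = NULL) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  edges <- .edge_matrix(edges)
  if (nrow(edges) > 0L) {
    .check_edge_endpoints(edges, gene_ids)
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, c(2L, 1L), drop = FALSE]
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  structure(list(gene_ids = gene_ids, edges = edges),
            class = "undirected_network")
}

#' Construct a directed network
#'
#' A directed network over a gene universe; each edge is an ordered
#' parent -> child pair. When `require_acyclic = TRUE` (the default for
#' search states and results) the edge set must admit a topological order.
#'
#' @param gene_ids Character vector of the gene universe.
#' @param edges Two-column character matrix/data.frame of (parent, child)
#'   pairs; may be empty.
#' @param require_acyclic Assert acyclicity (default `TRUE`).
#' @return An object of class `"directed_network"` with fields `gene_ids`
#'   and `edges`.
#' @export
directed_network <- function(gene_ids, edges = NULL, require_acyclic = TRUE) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  edges <- .edge_matrix(edges)
  if (nrow(edges) > 0L) {
    .check_edge_endpoints(edges, gene_ids)
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  net <- structure(list(gene_ids = gene_ids, edges = edges),
                   class = "directed_network")
  if (require_acyclic && !is_acyclic(net)) stop("directed network contains a cycle")
  net
}

#' Test whether a directed network is acyclic
#'
#' Kahn-style topological sort over the edge set.
#'
#' @param net A `directed_network` (acyclicity not pre-assumed).
#' @return `TRUE` if a topological order exists, else `FALSE`.
#' @export
is_acyclic <- function(net) {
  m <- length(net$gene_ids)
  if (nrow(net$edges) == 0L) return(TRUE)
  from <- match(net$edges[, 1L], net$gene_ids)
  to <- match(net$edges[, 2L], net$gene_ids)
  indeg <- tabulate(to, nbins = m)
  children <- split(to, factor(from, levels = seq_len(m)))
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen == m
}

#' @export
print.undirected_network <- function(x, ...) {
  cat("<undirected_network> ", length(x$gene_ids), " genes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @export
print.directed_network <- function(x, ...) {
  cat("<directed_network> ", length(x$gene_ids), " genes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Construct a scored network
#'
#' A directed acyclic network carrying its total score H and the per-node
#' local subnetwork scores. The total must equal the sum of the local scores
#' (checked to 1e-9 relative tolerance).
#'
#' @param network A `directed_network`.
#' @param h_score Total network score (sum of local scores).
#' @param local_scores Named numeric vector, one local score per gene.
#' @param restart_scores Optional numeric vector of the scores attained by
#'   each search restart (diagnostic).
#' @param restart_networks Optional list of the per-restart networks.
#' @return An object of class `"scored_network"`.
#' @export
scored_network <- function(network, h_score, local_scores,
                           restart_scores = NULL, restart_networks = NULL) {
  stopifnot(inherits(network, "directed_network"))
  if (!setequal(names(local_scores), network$gene_ids)) {
    stop("local_scores must be named by the network's genes")
  }
  local_scores <- local_scores[network$gene_ids]
  tot <- sum(local_scores)
  tol <- 1e-9 * max(1, abs(tot))
  if (abs(h_score - tot) > tol) {
    stop("h_score (", h_score, ") != sum of local scores (", tot, ")")
  }
  structure(list(network = network, h_score = h_score,
                 local_scores = local_scores,
                 restart_scores = restart_scores,
                 restart_networks = restart_networks),
            class = "scored_network")
}

#' @export
print.scored_network <- function(x, ...) {
  cat("<scored_network> H = ", format(x$h_score, digits = 6), ", ",
      nrow(x$network$edges), " edges over ",
      length(x$network$gene_ids), " genes\n", sep = "")
  invisible(x)
}
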