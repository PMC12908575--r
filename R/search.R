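# Restart hill-climbing over DAGs constrained to the CBN skeleton.
#
# Moves are the classic add / delete / reverse single-edge operations, with
# add and reverse restricted to pairs present in the skeleton and filtered
# for acyclicity by an incremental reachability check. At each iteration the
# best move in each of the three categories is found, the category winners
# are compared, and the overall winner is accepted iff it lowers H by more
# than a small tolerance; the climb stops at the first iteration with no
# accepting move. Scoring is incremental: a move rescores only the nodes
# whose parent set it touches, and local scores are memoised per
# (child, parent-set) so repeated candidate evaluations across iterations
# are free. Ties are broken lexicographically on (move kind with
# add < delete < reverse, source id, target id) so results are fully
# deterministic given data, parameters and seed.

#' Search parameters
#'
#' @param n_restarts_I Number of independent restarts (default 10).
#' @param init_edge_prob Probability that a skeleton edge is included in a
#'   random initial DAG (default 0.5).
#' @param max_iterations Hard cap on hill-climb iterations (default 1000).
#' @param improvement_tol Minimum score decrease counted as an improvement
#'   (default 1e-9, absolute); prevents floating-point churn.
#' @param seed Integer seed driving all randomness (restart initial DAGs).
#' @return A list of class `"search_params"`.
#' @export
search_params <- function(n_restarts_I = 10L, init_edge_prob = 0.5,
                          max_iterations = 1000L, improvement_tol = 1e-9,
                          seed = 1L) {
  stopifnot(n_restarts_I >= 1L, init_edge_prob >= 0, init_edge_prob <= 1,
            max_iterations >= 1L, improvement_tol > 0)
  structure(list(n_restarts_I = as.integer(n_restarts_I),
                 init_edge_prob = init_edge_prob,
                 max_iterations = as.integer(max_iterations),
                 improvement_tol = improvement_tol,
                 seed = as.integer(seed)),
            class = "search_params")
}

# derive a per-component seed from a master seed; kept inside 32-bit range
.derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.numeric(seed)
  for (k in ks) s <- (s * 69069 + 104729 * as.numeric(k) + 1) %% 2147483647
  as.integer(s)
}

#' Random initial DAG conforming to a skeleton
#'
#' Draws a uniform random topological order over the genes, then includes
#' each skeleton edge independently with probability `init_edge_prob`,
#' oriented from the earlier to the later gene in that order. Acyclic by
#' construction and deterministic given the seed.
#'
#' @param cbn An `undirected_network` (the skeleton).
#' @param init_edge_prob Edge inclusion probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A `directed_network` whose skeleton is a subset of `cbn`.
#' @export
random_initial_dag <- function(cbn, init_edge_prob = 0.5, seed = 1L) {
  genes <- cbn$gene_ids
  set.seed(seed)
  ord <- sample.int(length(genes))          # ord[i] = rank of gene i
  rank <- integer(length(genes)); rank[ord] <- seq_along(genes)
  ne <- nrow(cbn$edges)
  if (ne == 0L) return(directed_network(genes, NULL))
  keep <- stats::runif(ne) < init_edge_prob
  edges <- cbn$edges[keep, , drop = FALSE]
  if (nrow(edges) > 0L) {
    r1 <- rank[match(edges[, 1L], genes)]
    r2 <- rank[match(edges[, 2L], genes)]
    swap <- r1 > r2
    edges[swap, ] <- edges[swap, c(2L, 1L), drop = FALSE]
  }
  directed_network(genes, edges)
}

## ---- internal engine -------------------------------------------------------

# memoised local-score engine over a centered genes x samples matrix
.engine_new <- function(expr, params) {
  x <- unclass(expr)
  if (params$center_genes) x <- .center_rows(x)
  list(x = x, genes = rownames(x), n = ncol(x),
       logn = log(ncol(x)), lambda = params$lambda_reg,
       cache = new.env(parent = emptyenv()))
}

.engine_local <- function(eng, child, parents) {
  parents <- sort.int(parents)
  key <- paste0(child, "|", paste(parents, collapse = ","))
  val <- get0(key, envir = eng$cache, inherits = FALSE)
  if (!is.null(val)) return(val)
  val <- .rss(eng$x, child, parents) + eng$lambda * length(parents) * eng$logn
  assign(key, val, envir = eng$cache)
  val
}

# does a directed path from `from` to `to` exist? (iterative DFS over the
# children lists; `skip_child_of_from` drops one direct edge from -> skip)
.path_exists <- function(children, from, to, skip = 0L) {
  if (from == to) return(TRUE)
  first <- children[[from]]
  if (skip > 0L) first <- first[first != skip]
  stack <- first
  seen <- logical(length(children))
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (!seen[v]) {
      seen[v] <- TRUE
      stack <- c(stack, children[[v]])
    }
  }
  FALSE
}

# DAG state: integer parent/children adjacency + per-node local scores
.state_new <- function(dag, eng) {
  genes <- eng$genes
  m <- length(genes)
  parents <- rep(list(integer(0)), m)
  children <- rep(list(integer(0)), m)
  if (nrow(dag$edges) > 0L) {
    from <- match(dag$edges[, 1L], genes)
    to <- match(dag$edges[, 2L], genes)
    for (k in seq_along(from)) {
      parents[[to[k]]] <- c(parents[[to[k]]], from[k])
      children[[from[k]]] <- c(children[[from[k]]], to[k])
    }
  }
  locals <- vapply(seq_len(m), function(i) .engine_local(eng, i, parents[[i]]),
                   numeric(1))
  list(parents = parents, children = children, locals = locals)
}

.state_to_network <- function(state, genes) {
  eds <- do.call(rbind, lapply(seq_along(genes), function(v) {
    ps <- state$parents[[v]]
    if (length(ps) == 0L) NULL else cbind(genes[ps], genes[v])
  }))
  directed_network(genes, eds)
}

# ordered-pair scan orders, lexicographic on (source id, target id)
.lex_order <- function(from_id, to_id) order(from_id, to_id)

# enumerate candidate moves of one category with their score deltas;
# returns the best (delta, from, to) or NULL. Scanned in lexicographic
# order so the first strict minimum wins ties.
.best_add <- function(state, eng, cand) {
  # cand: 2-col integer matrix of candidate directed additions, lex-sorted
  best <- NULL
  for (k in seq_len(nrow(cand))) {
    u <- cand[k, 1L]; v <- cand[k, 2L]
    if (u %in% state$parents[[v]] || v %in% state$parents[[u]]) next
    if (.path_exists(state$children, v, u)) next
    delta <- .engine_local(eng, v, c(state$parents[[v]], u)) - state$locals[v]
    if (is.null(best) || delta < best$delta) best <- list(delta = delta, from = u, to = v)
  }
  best
}

.best_delete <- function(state, eng, edge_scan) {
  best <- NULL
  for (k in seq_len(nrow(edge_scan))) {
    u <- edge_scan[k, 1L]; v <- edge_scan[k, 2L]
    delta <- .engine_local(eng, v, setdiff(state$parents[[v]], u)) - state$locals[v]
    if (is.null(best) || delta < best$delta) best <- list(delta = delta, from = u, to = v)
  }
  best
}

.best_reverse <- function(state, eng, edge_scan) {
  best <- NULL
  for (k in seq_len(nrow(edge_scan))) {
    u <- edge_scan[k, 1L]; v <- edge_scan[k, 2L]
    # reversing u->v is legal iff no alternative path u ~> v remains
    if (.path_exists(state$children, u, v, skip = v)) next
    delta <- (.engine_local(eng, v, setdiff(state$parents[[v]], u)) - state$locals[v]) +
      (.engine_local(eng, u, c(state$parents[[u]], v)) - state$locals[u])
    if (is.null(best) || delta < best$delta) best <- list(delta = delta, from = u, to = v)
  }
  best
}

# current directed edges as an integer matrix scanned in lexicographic order
.edge_scan <- function(state, genes) {
  eds <- do.call(rbind, lapply(seq_along(genes), function(v) {
    ps <- state$parents[[v]]
    if (length(ps) == 0L) NULL else cbind(ps, v)
  }))
  if (is.null(eds)) return(matrix(integer(0), ncol = 2L))
  eds[.lex_order(genes[eds[, 1L]], genes[eds[, 2L]]), , drop = FALSE]
}

.apply_move_state <- function(state, eng, kind, u, v) {
  if (kind == "add") {
    state$parents[[v]] <- c(state$parents[[v]], u)
    state$children[[u]] <- c(state$children[[u]], v)
    state$locals[v] <- .engine_local(eng, v, state$parents[[v]])
  } else if (kind == "delete") {
    state$parents[[v]] <- setdiff(state$parents[[v]], u)
    state$children[[u]] <- setdiff(state$children[[u]], v)
    state$locals[v] <- .engine_local(eng, v, state$parents[[v]])
  } else {                                   # reverse u->v to v->u
    state$parents[[v]] <- setdiff(state$parents[[v]], u)
    state$children[[u]] <- setdiff(state$children[[u]], v)
    state$parents[[u]] <- c(state$parents[[u]], v)
    state$children[[v]] <- c(state$children[[v]], u)
    state$locals[v] <- .engine_local(eng, v, state$parents[[v]])
    state$locals[u] <- .engine_local(eng, u, state$parents[[u]])
  }
  state
}

## ---- public search surface -------------------------------------------------

#' Enumerate legal moves from a search state
#'
#' Returns the three move categories of the hill climber: additions of
#' skeleton pairs absent from the DAG (either orientation, acyclicity
#' preserved), deletions of present edges, and acyclicity-preserving
#' reversals.
#'
#' @param dag A `directed_network` whose skeleton is contained in `cbn`.
#' @param cbn The `undirected_network` skeleton.
#' @return Named list with data frames `add`, `delete`, `reverse`, each with
#'   character columns `from`, `to`.
#' @export
enumerate_moves <- function(dag, cbn) {
  genes <- cbn$gene_ids
  eng <- list(genes = genes)
  m <- length(genes)
  parents <- rep(list(integer(0)), m)
  children <- rep(list(integer(0)), m)
  if (nrow(dag$edges) > 0L) {
    from <- match(dag$edges[, 1L], genes)
    to <- match(dag$edges[, 2L], genes)
    for (k in seq_along(from)) {
      parents[[to[k]]] <- c(parents[[to[k]]], from[k])
      children[[from[k]]] <- c(children[[from[k]]], to[k])
    }
  }
  cand <- .candidate_additions(cbn, genes)
  add <- list()
  for (k in seq_len(nrow(cand))) {
    u <- cand[k, 1L]; v <- cand[k, 2L]
    if (u %in% parents[[v]] || v %in% parents[[u]]) next
    if (.path_exists(children, v, u)) next
    add[[length(add) + 1L]] <- c(genes[u], genes[v])
  }
  state <- list(parents = parents, children = children)
  eds <- .edge_scan(state, genes)
  del <- lapply(seq_len(nrow(eds)), function(k) genes[eds[k, ]])
  rev <- list()
  for (k in seq_len(nrow(eds))) {
    u <- eds[k, 1L]; v <- eds[k, 2L]
    if (!.path_exists(children, u, v, skip = v)) {
      rev[[length(rev) + 1L]] <- c(genes[u], genes[v])
    }
  }
  as_df <- function(lst) {
    if (length(lst) == 0L) {
      data.frame(from = character(0), to = character(0),
                 stringsAsFactors = FALSE)
    } else {
      m2 <- do.call(rbind, lst)
      data.frame(from = m2[, 1L], to = m2[, 2L], stringsAsFactors = FALSE)
    }
  }
  list(add = as_df(add), delete = as_df(del), reverse = as_df(rev))
}

#' Apply a single move to a directed network
#'
#' @param dag A `directed_network`.
#' @param kind One of `"add"`, `"delete"`, `"reverse"`.
#' @param from,to Gene ids of the (ordered) edge the move targets.
#' @return The modified `directed_network` (validated acyclic).
#' @export
apply_move <- function(dag, kind, from, to) {
  kind <- match.arg(kind, c("add", "delete", "reverse"))
  edges <- dag$edges
  has <- nrow(edges) > 0L && any(edges[, 1L] == from & edges[, 2L] == to)
  if (kind == "add") {
    if (has) stop("edge already present")
    edges <- rbind(edges, c(from, to))
  } else {
    if (!has) stop("edge not present")
    edges <- edges[!(edges[, 1L] == from & edges[, 2L] == to), , drop = FALSE]
    if (kind == "reverse") edges <- rbind(edges, c(to, from))
  }
  directed_network(dag$gene_ids, edges)
}

# both orientations of every skeleton pair, lexicographically sorted
.candidate_additions <- function(cbn, genes) {
  if (nrow(cbn$edges) == 0L) return(matrix(integer(0), ncol = 2L))
  i <- match(cbn$edges[, 1L], genes)
  j <- match(cbn$edges[, 2L], genes)
  cand <- rbind(cbind(i, j), cbind(j, i))
  cand[.lex_order(genes[cand[, 1L]], genes[cand[, 2L]]), , drop = FALSE]
}

#' Hill-climb from an initial DAG
#'
#' Greedy local search minimising the network score H. At each iteration the
#' best addition, best deletion and best reversal are identified, the best
#' of the three is taken, and it is accepted iff it improves H by more than
#' `improvement_tol`; otherwise the climb has converged. The H trajectory is
#' non-increasing by construction and is attached to the result as
#' `attr(, "trajectory")`.
#'
#' @param initial Acyclic `directed_network` with skeleton contained in
#'   `cbn`.
#' @param cbn The `undirected_network` skeleton.
#' @param expr Expression matrix for the stage being modelled.
#' @param score_params A [score_params()] object.
#' @param search_params A [search_params()] object (`max_iterations` and
#'   `improvement_tol` are used here).
#' @param engine Internal: a prebuilt score engine to share the memo cache
#'   across restarts.
#' @return A [scored_network()] whose H is less than or equal to the
#'   initial network's.
#' @export
hill_climb <- function(initial, cbn, expr, score_params = bcti::score_params(),
                       search_params = bcti::search_params(), engine = NULL) {
  eng <- if (is.null(engine)) .engine_new(expr, score_params) else engine
  genes <- eng$genes
  if (!setequal(cbn$gene_ids, genes)) stop("skeleton genes must match the data")
  state <- .state_new(initial, eng)
  cand <- .candidate_additions(cbn, genes)
  h <- sum(state$locals)
  traj <- h
  tol <- search_params$improvement_tol
  for (it in seq_len(search_params$max_iterations)) {
    eds <- .edge_scan(state, genes)
    cands <- list(add = .best_add(state, eng, cand),
                  delete = .best_delete(state, eng, eds),
                  reverse = .best_reverse(state, eng, eds))
    best_kind <- NULL; best <- NULL
    for (kind in c("add", "delete", "reverse")) {
      b <- cands[[kind]]
      if (!is.null(b) && (is.null(best) || b$delta < best$delta)) {
        best <- b; best_kind <- kind
      }
    }
    if (is.null(best) || best$delta >= -tol) break
    state <- .apply_move_state(state, eng, best_kind, best$from, best$to)
    h <- h + best$delta
    traj <- c(traj, h)
    if (it == search_params$max_iterations) {
      warning("hill climb hit max_iterations before converging")
    }
  }
  net <- .state_to_network(state, genes)
  res <- scored_network(net, sum(state$locals), stats::setNames(state$locals, genes))
  attr(res, "trajectory") <- traj
  res
}

#' Infer the globally optimal network for one expression matrix
#'
#' Builds the CBN skeleton once, runs `n_restarts_I` independent seeded
#' hill climbs from random initial DAGs, and returns the restart with the
#' minimal H (ties broken by restart index). The per-restart scores and
#' networks are kept on the result for the restart-consistency diagnostic.
#'
#' @param expr Expression matrix (genes x samples).
#' @param mi_params An [mi_params()] object (skeleton construction).
#' @param score_params A [score_params()] object.
#' @param search_params A [search_params()] object; its `seed` drives the
#'   restart initial DAGs.
#' @param cbn Optional precomputed skeleton (skips [build_cbn()]).
#' @return A [scored_network()] with `restart_scores` and
#'   `restart_networks` populated.
#' @export
infer_global_optimum <- function(expr, mi_params = bcti::mi_params(),
                                 score_params = bcti::score_params(),
                                 search_params = bcti::search_params(),
                                 cbn = NULL) {
  if (is.null(cbn)) cbn <- build_cbn(expr, mi_params)
  eng <- .engine_new(expr, score_params)
  best <- NULL
  scores <- numeric(search_params$n_restarts_I)
  nets <- vector("list", search_params$n_restarts_I)
  for (k in seq_len(search_params$n_restarts_I)) {
    init <- random_initial_dag(cbn, search_params$init_edge_prob,
                               seed = .derive_seed(search_params$seed, k))
    res <- hill_climb(init, cbn, expr, score_params, search_params, engine = eng)
    scores[k] <- res$h_score
    nets[[k]] <- res$network
    if (is.null(best) || res$h_score < best$h_score) best <- res
  }
  scored_network(best$network, best$h_score, best$local_scores,
                 restart_scores = scores, restart_networks = nets)
}
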