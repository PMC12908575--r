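# Critical-state detection from the stage-wise trajectory of the optimal
# network score. The score at stage t, S(t), is the H score of the global
# optimal network inferred for that stage. As a system approaches a tipping
# point, a core subnetwork shows inflated per-gene variance and inflated
# inter-gene correlation; since the score is positively correlated with
# expression variance, S(t) surges, and the enhanced collinearity among
# core genes destabilises the structure search (lower restart agreement,
# lower recovery of true edges). The primary call is the score test; the
# structural-instability metrics are reported as corroboration.

#' Detection parameters
#'
#' @param alpha Significance level for the score test (default 0.05).
#' @param sided `"two"` (default) or `"greater"` (one-sided: the current
#'   score exceeds the historical mean, the direction the theory predicts).
#' @param min_history Minimum number of earlier stages required before a
#'   stage is testable (default 2, so the first testable stage is the
#'   third).
#' @return A list of class `"detection_params"`.
#' @export
detection_params <- function(alpha = 0.05, sided = c("two", "greater"),
                             min_history = 2L) {
  sided <- match.arg(sided)
  stopifnot(alpha > 0, alpha < 1, min_history >= 2L)
  structure(list(alpha = alpha, sided = sided,
                 min_history = as.integer(min_history)),
            class = "detection_params")
}

#' One-sample t-test of the score history against the current score
#'
#' The scores of the earlier stages form the sample; the current score is
#' the hypothesised mean. With a history of length `t - 1` the statistic has
#' `t - 2` degrees of freedom. A zero-variance history is degenerate: the
#' p-value is 1 when the current score equals the historical value (within
#' 1e-12) and 0 otherwise.
#'
#' @param history Numeric vector of earlier scores (length >= 2).
#' @param current The current score (hypothesised mean).
#' @param sided `"two"` or `"greater"`.
#' @return p-value in \[0, 1\].
#' @export
ttest_pvalue <- function(history, current, sided = c("two", "greater")) {
  sided <- match.arg(sided)
  k <- length(history)
  if (k < 2L) stop("history must contain at least 2 scores")
  mu <- mean(history)
  s <- stats::sd(history)
  if (s == 0) {
    return(if (abs(current - mu) <= 1e-12) 1 else 0)
  }
  tstat <- (mu - current) / (s / sqrt(k))
  df <- k - 1L
  if (sided == "two") 2 * stats::pt(-abs(tstat), df) else stats::pt(tstat, df)
}

#' Compute the score trajectory across stages
#'
#' Runs one full network inference per stage (per-stage skeleton, seeded
#' restarts) and assembles the stage-wise score series together with the
#' per-stage test p-values and instability diagnostics. The per-stage seed
#' is derived deterministically from the master seed in `search_params` and
#' the stage index, so the whole series is reproducible.
#'
#' @param data A [staged_dataset()].
#' @param mi_params An [mi_params()] object.
#' @param score_params A [score_params()] object.
#' @param search_params A [search_params()] object; its `seed` is the master
#'   seed.
#' @param detection_params A [detection_params()] object.
#' @param reference Optional gold-standard `directed_network`; when given,
#'   the per-stage true-positive rate against it is reported as the
#'   instability metric alongside restart consistency.
#' @param equalize_n If `TRUE`, every stage is subsampled (seeded) to the
#'   minimum stage size before inference, making raw scores comparable when
#'   stage sizes differ; default `FALSE` (raw scores, which scale with the
#'   per-stage sample count).
#' @return An object of class `"bcti_series"`: list with `stage_labels`,
#'   `scores_S`, `p_values` (NA where not yet testable), `restart_consistency`,
#'   `tpr` (NA if no reference), and `networks` (per-stage scored networks).
#' @export
compute_bcti_series <- function(data, mi_params = bcti::mi_params(),
                                score_params = bcti::score_params(),
                                search_params = bcti::search_params(),
                                detection_params = bcti::detection_params(),
                                reference = NULL, equalize_n = FALSE) {
  stopifnot(inherits(data, "staged_dataset"))
  labels <- data$stage_labels
  tmax <- length(labels)
  if (equalize_n) {
    nmin <- min(vapply(data$blocks, ncol, integer(1)))
    data$blocks <- lapply(seq_along(data$blocks), function(i) {
      b <- data$blocks[[i]]
      set.seed(.derive_seed(search_params$seed, 777L, i))
      keep <- sort(sample.int(ncol(b), nmin))
      expression_matrix(unclass(b)[, keep, drop = FALSE])
    })
    names(data$blocks) <- labels
  }
  networks <- vector("list", tmax)
  scores <- numeric(tmax)
  consistency <- numeric(tmax)
  tprs <- rep(NA_real_, tmax)
  genes <- rownames(data$blocks[[1L]])
  for (t in seq_len(tmax)) {
    sp <- search_params
    sp$seed <- .derive_seed(search_params$seed, t)
    fit <- infer_global_optimum(data$blocks[[t]], mi_params, score_params, sp)
    networks[[t]] <- fit
    scores[t] <- fit$h_score
    consistency[t] <- restart_consistency(fit$restart_networks)
    if (!is.null(reference)) {
      tprs[t] <- structural_instability(fit$network, reference, genes)
    }
  }
  pvals <- rep(NA_real_, tmax)
  first_t <- detection_params$min_history + 1L
  if (tmax >= first_t) {
    for (t in seq(first_t, tmax)) {
      pvals[t] <- ttest_pvalue(scores[seq_len(t - 1L)], scores[t],
                               detection_params$sided)
    }
  }
  structure(list(stage_labels = labels, scores_S = scores, p_values = pvals,
                 restart_consistency = consistency, tpr = tprs,
                 networks = networks),
            class = "bcti_series")
}

#' @export
print.bcti_series <- function(x, ...) {
  df <- data.frame(stage = x$stage_labels,
                   S = signif(x$scores_S, 6),
                   p = signif(x$p_values, 4),
                   consistency = signif(x$restart_consistency, 4),
                   tpr = signif(x$tpr, 4))
  cat("<bcti_series>\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Call the critical state from a score series
#'
#' The earliest testable stage whose p-value falls below `alpha` is called
#' critical; `NA` if no stage qualifies. When instability diagnostics are
#' present, the call reports whether they corroborate it (restart
#' consistency, and the true-positive rate if a reference was supplied, both
#' lower at the called stage than their mean over the earlier stages); the
#' corroboration is informative, not a gate.
#'
#' @param series A `bcti_series`.
#' @param params A [detection_params()] object.
#' @return List with `critical_stage` (label or `NA`), `critical_index`,
#'   `p_values` (per stage), and `corroborated` (logical or `NA`).
#' @export
detect_critical_state <- function(series, params = detection_params()) {
  stopifnot(inherits(series, "bcti_series"))
  if (length(series$stage_labels) < 3L) stop("need at least 3 stages")
  pv <- series$p_values
  hit <- which(!is.na(pv) & pv < params$alpha)
  if (length(hit) == 0L) {
    return(list(critical_stage = NA_character_, critical_index = NA_integer_,
                p_values = pv, corroborated = NA))
  }
  t <- hit[1L]
  corro <- NA
  if (!is.null(series$restart_consistency) && t > 1L) {
    pre <- mean(series$restart_consistency[seq_len(t - 1L)])
    corro <- series$restart_consistency[t] < pre
    if (!all(is.na(series$tpr))) {
      pre_tpr <- mean(series$tpr[seq_len(t - 1L)], na.rm = TRUE)
      corro <- corro || isTRUE(series$tpr[t] < pre_tpr)
    }
  }
  list(critical_stage = series$stage_labels[t], critical_index = t,
       p_values = pv, corroborated = corro)
}

#' Structural instability as recovery of a reference network
#'
#' True-positive rate of the stage network against a (nonempty) reference
#' gold standard over ordered gene pairs; a drop signals that enhanced
#' collinearity is destabilising structure recovery.
#'
#' @param network_t `directed_network` inferred at the stage.
#' @param reference Nonempty gold-standard `directed_network`.
#' @param gene_universe Character vector of the gene universe.
#' @return TPR in \[0, 1\].
#' @export
structural_instability <- function(network_t, reference, gene_universe) {
  if (nrow(reference$edges) == 0L) stop("reference network must be nonempty")
  tpr(confusion_counts(network_t, reference, gene_universe))
}

#' Restart consistency of a set of search results
#'
#' Mean pairwise Jaccard similarity of the directed edge sets across
#' restarts; 1 means every restart found the same network, and low values
#' flag an unstable search landscape. Two empty edge sets count as
#' identical.
#'
#' @param networks List of at least two `directed_network` objects over the
#'   same gene universe.
#' @return Mean pairwise Jaccard index in \[0, 1\].
#' @export
restart_consistency <- function(networks) {
  if (length(networks) < 2L) stop("need at least 2 restart networks")
  sets <- lapply(networks, function(nw) {
    if (nrow(nw$edges) == 0L) character(0)
    else paste(nw$edges[, 1L], nw$edges[, 2L], sep = "->")
  })
  pairs <- utils::combn(length(sets), 2L)
  jac <- apply(pairs, 2L, function(ij) {
    a <- sets[[ij[1L]]]; b <- sets[[ij[2L]]]
    u <- length(union(a, b))
    if (u == 0L) 1 else length(intersect(a, b)) / u
  })
  mean(jac)
}
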