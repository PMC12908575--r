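# Confusion-matrix evaluation of a predicted directed network against a
# gold standard. The evaluation universe is all ordered gene pairs without
# self-pairs (m * (m - 1) pairs for m genes) and matching is
# direction-sensitive: a reversed edge counts as both a false positive and
# a false negative.

#' Confusion counts over ordered gene pairs
#'
#' @param predicted `directed_network` of predicted edges.
#' @param gold `directed_network` of gold-standard edges.
#' @param gene_universe Character vector of the m genes defining the
#'   evaluation universe; both edge sets must lie inside it.
#' @return List of class `"confusion_counts"` with integer fields `tp`,
#'   `fp`, `fn`, `tn` summing to `m * (m - 1)`.
#' @export
confusion_counts <- function(predicted, gold, gene_universe) {
  gene_universe <- as.character(gene_universe)
  m <- length(gene_universe)
  key <- function(net) {
    .check_edge_endpoints(net$edges, gene_universe)
    if (nrow(net$edges) == 0L) character(0)
    else paste(net$edges[, 1L], net$edges[, 2L], sep = "\r")
  }
  p <- key(predicted)
  g <- key(gold)
  tp <- length(intersect(p, g))
  fp <- length(setdiff(p, g))
  fn <- length(setdiff(g, p))
  tn <- m * (m - 1L) - tp - fp - fn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("TP=", x$tp, " FP=", x$fp, " FN=", x$fn, " TN=", x$tn, "\n", sep = "")
  invisible(x)
}

#' True positive rate
#'
#' `TP / (TP + FN)`: the fraction of gold-standard directed edges recovered.
#'
#' @param counts A `confusion_counts` object.
#' @return TPR in \[0, 1\]; error if the gold standard is empty
#'   (`TP + FN = 0`).
#' @export
tpr <- function(counts) {
  denom <- counts$tp + counts$fn
  if (denom == 0L) stop("TPR undefined: empty gold standard (tp + fn = 0)")
  counts$tp / denom
}

#' Accuracy of a network prediction
#'
#' Default `"overall"`: `(TP + TN) / (TP + FP + FN + TN)` over all ordered
#' pairs. The alternative `"precision"` definition, `TP / (TP + FP)`, is the
#' fraction of predicted edges that are correct.
#'
#' @param counts A `confusion_counts` object.
#' @param type `"overall"` (default) or `"precision"`.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(counts, type = c("overall", "precision")) {
  type <- match.arg(type)
  if (type == "overall") {
    total <- counts$tp + counts$fp + counts$fn + counts$tn
    if (total == 0L) stop("empty evaluation universe")
    (counts$tp + counts$tn) / total
  } else {
    denom <- counts$tp + counts$fp
    if (denom == 0L) stop("precision undefined: no predicted edges")
    counts$tp / denom
  }
}
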