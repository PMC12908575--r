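# Correlation basis network: pairwise Gaussian mutual information thresholded
# at T. Under the Gaussian assumption the mutual information of a gene pair
# reduces to a closed form of the Pearson correlation,
#   I(rho) = -1/2 * log(1 - rho^2 + epsilon),
# with a small epsilon guard keeping the log finite as |rho| -> 1. Natural
# logarithms throughout, so I and the threshold T are in nats.

#' Mutual-information parameters
#'
#' @param epsilon Guard constant added inside the log (default `1e-5`);
#'   must be positive.
#' @param threshold_T Mutual-information threshold in nats for skeleton
#'   edges (default `0.1`); must be non-negative.
#' @return A list of class `"mi_params"`.
#' @export
mi_params <- function(epsilon = 1e-5, threshold_T = 0.1) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            is.numeric(threshold_T), length(threshold_T) == 1L, threshold_T >= 0)
  structure(list(epsilon = epsilon, threshold_T = threshold_T),
            class = "mi_params")
}

#' Gaussian mutual information from a Pearson correlation
#'
#' Closed-form mutual information of a bivariate Gaussian pair,
#' `-0.5 * log(1 - rho^2 + epsilon)` (natural log). Symmetric in the sign of
#' `rho` and monotonically increasing in `|rho|`. The epsilon guard makes the
#' value finite at `|rho| = 1` and slightly negative at `rho = 0`.
#'
#' @param rho Pearson correlation(s) in \[-1, 1\] (vectorized).
#' @param epsilon Positive guard constant (default `1e-5`).
#' @return Mutual information in nats, same length as `rho`.
#' @export
gaussian_mutual_information <- function(rho, epsilon = 1e-5) {
  stopifnot(epsilon > 0)
  if (any(abs(rho) > 1 + 1e-12)) {
    stop("|rho| > 1: ", paste(rho[abs(rho) > 1 + 1e-12], collapse = ", "))
  }
  rho <- pmin(pmax(rho, -1), 1)
  -0.5 * log(1 - rho^2 + epsilon)
}

#' Pairwise Gaussian mutual information matrix
#'
#' Computes the Pearson correlation between every gene pair within the
#' matrix and maps it through [gaussian_mutual_information()]. The diagonal
#' is 0 by convention. A gene with zero variance has no defined correlation;
#' it is treated as independent of everything (`rho = 0`) with a warning.
#'
#' @param expr An expression matrix (genes x samples).
#' @param params An [mi_params()] object.
#' @return Symmetric m x m numeric matrix of mutual information values with
#'   gene ids as dimnames.
#' @export
pairwise_mi <- function(expr, params = mi_params()) {
  x <- unclass(expr)
  sds <- apply(x, 1L, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning("constant gene(s) treated as independent: ",
            paste(rownames(x)[const], collapse = ", "))
  }
  rho <- matrix(0, nrow(x), nrow(x), dimnames = list(rownames(x), rownames(x)))
  ok <- !const
  if (sum(ok) >= 2L) {
    rho[ok, ok] <- stats::cor(t(x[ok, , drop = FALSE]))
  }
  mi <- gaussian_mutual_information(rho, params$epsilon)
  diag(mi) <- 0
  mi
}

#' Build the correlation basis network
#'
#' Thresholds the pairwise mutual-information matrix: the unordered pair
#' \{i, j\} is a skeleton edge iff `I(i, j) >= threshold_T`. The resulting
#' undirected network constrains which directed edges the structure search
#' may ever consider.
#'
#' @param expr An expression matrix.
#' @param params An [mi_params()] object.
#' @return An [undirected_network()].
#' @export
build_cbn <- function(expr, params = mi_params()) {
  mi <- pairwise_mi(expr, params)
  genes <- rownames(mi)
  idx <- which(upper.tri(mi) & mi >= params$threshold_T, arr.ind = TRUE)
  edges <- cbind(genes[idx[, 1L]], genes[idx[, 2L]])
  undirected_network(genes, edges)
}
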