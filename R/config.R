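# Run configuration: a YAML file holding the parameter blocks of every
# component plus a master seed, schema-checked (unknown keys are an error
# so typos cannot silently fall back to defaults).

.known_config_keys <- list(
  top = c("seed", "output_dir", "mi", "score", "search", "detection",
          "planted", "sde"),
  mi = c("epsilon", "threshold_T"),
  score = c("lambda_reg", "center_genes"),
  search = c("n_restarts_I", "init_edge_prob", "max_iterations",
             "improvement_tol", "seed"),
  detection = c("alpha", "sided", "min_history"),
  planted = c("m_genes", "n_samples_per_stage", "n_stages", "critical_stage",
              "beta", "baseline_sd", "variance_inflation",
              "correlation_boost", "seed"),
  sde = c("q_grid", "sigma_noise", "dt", "n_steps_per_q", "n_replicates",
          "seed")
)

.check_keys <- function(block, allowed, where) {
  bad <- setdiff(names(block), allowed)
  if (length(bad) > 0L) {
    stop("unknown configuration key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
  }
  block
}

#' Read and validate a run configuration
#'
#' Parses a YAML file with optional blocks `mi`, `score`, `search`,
#' `detection`, `planted`, `sde` plus top-level `seed` and `output_dir`.
#' Each block is passed through the matching parameter constructor, so
#' values are range-checked; unknown keys anywhere are rejected. The master
#' `seed` is copied into any block that takes one but does not set its own.
#'
#' @param path Path to a YAML file.
#' @return List with elements `seed`, `output_dir`, `mi`, `score`, `search`,
#'   `detection`, and (when present in the file) `planted` and `sde`
#'   argument lists for the simulator constructors.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("configuration must be a YAML mapping")
  .check_keys(raw, .known_config_keys$top, "top level")
  for (blk in intersect(names(raw), c("mi", "score", "search", "detection",
                                      "planted", "sde"))) {
    .check_keys(raw[[blk]], .known_config_keys[[blk]], paste0("'", blk, "'"))
  }
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  with_seed <- function(block) {
    if (is.null(block$seed)) block$seed <- seed
    block
  }
  cfg <- list(
    seed = seed,
    output_dir = if (is.null(raw$output_dir)) "." else raw$output_dir,
    mi = do.call(mi_params, raw$mi %||% list()),
    score = do.call(score_params, raw$score %||% list()),
    search = do.call(search_params, with_seed(raw$search %||% list())),
    detection = do.call(detection_params, raw$detection %||% list())
  )
  if (!is.null(raw$planted)) cfg$planted <- with_seed(raw$planted)
  if (!is.null(raw$sde)) cfg$sde <- with_seed(raw$sde)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
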