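# Readers/writers for the three tabular interchange formats: expression
# matrices (header = sample ids, first column = gene ids), stage maps
# (sample_id, stage_label) and edge lists (source, target). TSV is the
# default dialect; a comma dialect is auto-detected from the header line.

.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else if (grepl(",", header, fixed = TRUE)) "," else "\t"
}

#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample ids and a first column of gene ids
#' (genes-as-rows, the canonical orientation). Set `samples_as_rows = TRUE`
#' for the transposed layout. The field separator (tab or comma) is sniffed
#' from the header line. Missing or non-numeric cells are a hard error:
#' the network score is undefined on missing entries, so nothing is imputed.
#'
#' @param path Path to the file.
#' @param samples_as_rows If `TRUE`, the file has samples as rows and genes
#'   as columns; it is transposed on load.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, samples_as_rows = FALSE) {
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicated ", if (samples_as_rows) "sample" else "gene", " id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  body <- df[, -1L, drop = FALSE]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(vals) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(as.matrix(bad)) > 0L && length(bad) > 0L) {
    b <- as.matrix(bad)
    stop("non-numeric cell at row '", ids[b[1L, 1L]], "', column '",
         colnames(body)[b[1L, 2L]], "'")
  }
  rownames(vals) <- ids
  if (samples_as_rows) vals <- t(vals)
  expression_matrix(vals)
}

#' Write an expression matrix to TSV
#'
#' Genes as rows, header of sample ids, first column `gene_id`. Round-trips
#' through [read_expression()].
#'
#' @param expr An expression matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), unclass(expr),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-stage map
#'
#' Two-column table (sample_id, stage_label), tab- or comma-separated, with
#' or without a header line (a header is assumed when the first field of the
#' first line is literally `sample_id`).
#'
#' @param path Path to the file.
#' @return Named character vector mapping sample id to stage label.
#' @export
read_stage_map <- function(path) {
  sep <- .sniff_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  header <- identical(tolower(first[1L]), "sample_id")
  df <- utils::read.table(path, header = header, sep = sep,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("stage map needs two columns (sample_id, stage_label)")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write a sample-to-stage map
#'
#' @param stage_map Named character vector (names = sample ids, values =
#'   stage labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stage_map <- function(stage_map, path) {
  df <- data.frame(sample_id = names(stage_map), stage_label = unname(stage_map),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split an expression matrix into stage blocks
#'
#' Partitions the samples of `expr` by the stage map into one block per
#' stage, in the order given by `stage_order`. Gene order is preserved in
#' every block; each stage must end up with at least 3 samples.
#'
#' @param expr An expression matrix.
#' @param stage_map Named character vector sample id -> stage label.
#' @param stage_order Ordered character vector of stage labels (the time
#'   axis).
#' @return A [staged_dataset()].
#' @export
split_by_stage <- function(expr, stage_map, stage_order) {
  samples <- colnames(expr)
  unmapped <- setdiff(samples, names(stage_map))
  if (length(unmapped) > 0L) {
    stop("sample(s) missing from the stage map: ",
         paste(unmapped, collapse = ", "))
  }
  stages <- stage_map[samples]
  unknown <- setdiff(unique(stages), stage_order)
  if (length(unknown) > 0L) {
    stop("stage(s) not in stage_order: ", paste(unknown, collapse = ", "))
  }
  blocks <- lapply(stage_order, function(st) {
    keep <- samples[stages == st]
    if (length(keep) < 3L) {
      stop("stage '", st, "' has ", length(keep), " samples; at least 3 required")
    }
    expression_matrix(unclass(expr)[, keep, drop = FALSE])
  })
  names(blocks) <- stage_order
  staged_dataset(blocks, stage_order)
}

#' Read a network edge list
#'
#' Two-column (source, target) table; a third column, if present, is
#' ignored. Directedness is declared by the caller, never inferred: with
#' `directed = FALSE` the pairs `a b` and `b a` collapse to the single
#' undirected edge \{a, b\}. Self-loops are rejected. When `gene_ids` is
#' supplied it defines the gene universe and edges outside it are an error;
#' otherwise the universe is the set of genes seen in the file.
#'
#' @param path Path to the file.
#' @param directed Read as a directed network?
#' @param gene_ids Optional gene universe.
#' @param header Does the file start with a header line? Default `FALSE`.
#' @return An [undirected_network()] or [directed_network()].
#' @export
read_edge_list <- function(path, directed = TRUE, gene_ids = NULL,
                           header = FALSE) {
  info <- file.info(path)
  empty <- is.na(info$size) || info$size == 0L ||
    length(readLines(path, n = 1L)) == 0L
  if (empty) {
    edges <- NULL
  } else {
    sep <- .sniff_sep(path)
    df <- utils::read.table(path, header = header, sep = sep,
                            colClasses = "character", stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("edge list needs two columns (source, target)")
    edges <- as.matrix(df[, 1:2, drop = FALSE])
  }
  if (is.null(gene_ids)) gene_ids <- sort(unique(c(edges)))
  if (directed) directed_network(gene_ids, edges)
  else undirected_network(gene_ids, edges)
}

#' Write a network edge list
#'
#' Two-column TSV (source, target), no header. Round-trips through
#' [read_edge_list()] with the matching `directed` flag.
#'
#' @param net An `undirected_network` or `directed_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
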