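#' Read and write embedded graphs as delimited text
#'
#' On disk a graph is two tab-separated files: `<prefix>.nodes.tsv` with
#' columns `node_id, coord_1..coord_m` and `<prefix>.edges.tsv` with
#' columns `source_id, target_id`. Node ids are 0-based integers on disk
#' and converted to R's 1-based indices in memory.
#'
#' @param prefix path prefix of the two files.
#' @return [read_graph()] returns an [embedded_graph()]; [write_graph()]
#'   returns `prefix` invisibly.
#' @export
read_graph <- function(prefix) {
  nodes <- utils::read.delim(paste0(prefix, ".nodes.tsv"),
                             check.names = FALSE)
  edges <- utils::read.delim(paste0(prefix, ".edges.tsv"))
  o <- order(nodes$node_id)
  nodes <- nodes[o, , drop = FALSE]
  coords <- as.matrix(nodes[, setdiff(names(nodes), "node_id"), drop = FALSE])
  dimnames(coords) <- NULL
  ed <- if (nrow(edges) > 0L) {
    cbind(edges$source_id + 1L, edges$target_id + 1L)
  } else NULL
  embedded_graph(coords, ed)
}

#' @param graph an [embedded_graph()].
#' @rdname read_graph
#' @export
write_graph <- function(graph, prefix) {
  coords <- graph$node_coords
  nodes <- data.frame(node_id = seq_len(nrow(coords)) - 1L)
  for (j in seq_len(ncol(coords))) nodes[[paste0("coord_", j)]] <- coords[, j]
  utils::write.table(nodes, paste0(prefix, ".nodes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  ed <- data.frame(source_id = graph$edges[, 1L] - 1L,
                   target_id = graph$edges[, 2L] - 1L)
  utils::write.table(ed, paste0(prefix, ".edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Write a segment decomposition as TSV
#'
#' One row per segment: `segment_id` (0-based) and the ordered
#' comma-separated 0-based node ids of its path.
#'
#' @param decomposition a [decompose_into_segments()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_segments <- function(decomposition, path) {
  df <- data.frame(
    segment_id = seq_along(decomposition$segments) - 1L,
    node_ids = vapply(decomposition$segments,
                      function(p) paste(p - 1L, collapse = ","), character(1)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-point segment labels as TSV
#'
#' Columns `point_index` (0-based) and `segment_id` (0-based).
#'
#' @param labels a `"segment_labels"` object or plain label vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  lab <- extract_labels(labels)
  df <- data.frame(point_index = seq_along(lab) - 1L, segment_id = lab - 1L)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a delimited data matrix
#'
#' Reads a points-by-features numeric matrix from TSV or CSV, with or
#' without a header line.
#'
#' @param path input file; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @return Numeric matrix.
#' @export
read_points <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  has_header <- any(is.na(suppressWarnings(
    as.numeric(strsplit(first, sep, fixed = TRUE)[[1L]]))))
  as_points_matrix(utils::read.table(path, sep = sep, header = has_header))
}
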