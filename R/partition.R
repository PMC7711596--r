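#' Assign each data point to its nearest graph node
#'
#' Exact Euclidean nearest node per point; ties are broken by the smallest
#' node index.
#'
#' @param data numeric matrix of points (rows) in the graph's ambient space.
#' @param graph an [embedded_graph()].
#' @return List with `nearest_node` (integer per point) and `distance`
#'   (Euclidean distance to that node).
#' @export
assign_nearest_node <- function(data, graph) {
  x <- as_points_matrix(data)
  if (ncol(x) != ncol(graph$node_coords)) {
    stop(sprintf("data dimension (%d) does not match graph dimension (%d)",
                 ncol(x), ncol(graph$node_coords)))
  }
  d2 <- sq_dist_matrix(x, graph$node_coords)
  idx <- max.col(-d2, ties.method = "first")
  list(nearest_node = idx,
       distance = sqrt(d2[cbind(seq_len(nrow(x)), idx)]))
}

#' Cluster a data cloud by nearest graph segment
#'
#' The device that turns a graph approximation into a clustering: each point
#' is labelled by the segment of the graph nearest to it. Proximity is
#' defined through nodes: if the point's nearest node belongs to exactly one
#' segment, that segment is the label; if the nearest node is a branching
#' node shared by several segments, the point is labelled by the segment
#' (among those candidates) containing the next-nearest node, recursing to
#' the third-nearest and beyond if that node is again shared, and finally
#' falling back to the smallest candidate segment index. An alternative
#' proximity (`mode = "edge"`), assigning by the nearest point on any edge of
#' the piecewise-linear graph, is available for sensitivity checks.
#'
#' @param data numeric point matrix.
#' @param graph an [embedded_graph()].
#' @param decomposition optional precomputed [decompose_into_segments()]
#'   result for `graph`.
#' @param mode `"node"` (default; nearest node with the second-nearest rule)
#'   or `"edge"` (nearest point on an edge).
#' @return List of class `"segment_labels"` with `label` (integer per point,
#'   in `1..n_segments`) and `n_segments`.
#' @export
cluster_by_segments <- function(data, graph,
                                decomposition = decompose_into_segments(graph),
                                mode = c("node", "edge")) {
  mode <- match.arg(mode)
  x <- as_points_matrix(data)
  if (ncol(x) != ncol(graph$node_coords)) {
    stop("data dimension does not match graph dimension")
  }
  nseg <- n_segments(decomposition)
  if (nseg == 0L) stop("empty segment decomposition")

  if (mode == "edge") {
    label <- edge_mode_labels(x, graph, decomposition)
    return(structure(list(label = label, n_segments = nseg),
                     class = "segment_labels"))
  }

  d2 <- sq_dist_matrix(x, graph$node_coords)
  n2s <- decomposition$node_to_segments
  nearest <- max.col(-d2, ties.method = "first")
  label <- integer(nrow(x))
  shared <- vapply(n2s, length, integer(1)) > 1L

  simple <- !shared[nearest]
  label[simple] <- vapply(nearest[simple], function(v) n2s[[v]][1L], integer(1))

  for (i in which(!simple)) {
    cand <- n2s[[nearest[i]]]
    # nodes of candidate segments, ranked by distance; the first node lying
    # in a unique candidate segment decides; exhausted -> smallest id
    cand_nodes <- unique(unlist(decomposition$segments[cand]))
    cand_nodes <- setdiff(cand_nodes, nearest[i])
    lab <- NA_integer_
    if (length(cand_nodes) > 0L) {
      ord <- cand_nodes[order(d2[i, cand_nodes], cand_nodes)]
      for (v in ord) {
        inseg <- intersect(n2s[[v]], cand)
        if (length(inseg) == 1L) { lab <- inseg; break }
      }
    }
    label[i] <- if (is.na(lab)) min(cand) else lab
  }
  structure(list(label = label, n_segments = nseg), class = "segment_labels")
}

# nearest point-on-edge assignment (the "theoretically better" proximity)
edge_mode_labels <- function(x, graph, decomposition) {
  ed <- graph$edges
  if (nrow(ed) == 0L) stop("edge-mode assignment needs at least one edge")
  n <- nrow(x)
  best_d2 <- rep(Inf, n)
  best_seg <- integer(n)
  for (e in seq_len(nrow(ed))) {
    a <- graph$node_coords[ed[e, 1L], ]
    b <- graph$node_coords[ed[e, 2L], ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, n) else
      pmin(1, pmax(0, (sweep(x, 2L, a) %*% ab) / len2))
    proj <- outer(drop(t), ab) + rep(a, each = n)
    d2 <- rowSums((x - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_seg[upd] <- decomposition$edge_to_segment[e]
  }
  best_seg
}

#' @export
print.segment_labels <- function(x, ...) {
  cat(sprintf("Segment labels: %d points over %d segments\n",
              length(x$label), x$n_segments))
  print(table(segment = x$label))
  invisible(x)
}

#' Compare two graph approximations on a dataset
#'
#' The three-step graph comparison: decompose each graph into segments,
#' cluster the data cloud by nearest segment for each, then compare the two
#' induced clusterings with a standard score. Because the clusterings are
#' induced by segments, the score depends on the trajectories the graphs
#' trace, not on their node/edge bookkeeping — refining a graph with extra
#' degree-2 nodes leaves the score essentially unchanged.
#'
#' @param data numeric point matrix.
#' @param graph_a,graph_b [embedded_graph()]s in the same ambient space as
#'   `data`.
#' @param metric one of `"adjusted_rand"` (default), `"adjusted_mutual_information"`,
#'   `"fowlkes_mallows"`, `"v_measure"`.
#' @param mode proximity mode passed to [cluster_by_segments()].
#' @return The comparison score (symmetric in the two graphs; 1 for
#'   identical induced clusterings, near 0 for unrelated ones for the
#'   adjusted metrics).
#' @export
compare_graphs_on_data <- function(data, graph_a, graph_b,
                                   metric = "adjusted_rand",
                                   mode = c("node", "edge")) {
  mode <- match.arg(mode)
  la <- cluster_by_segments(data, graph_a, mode = mode)
  lb <- cluster_by_segments(data, graph_b, mode = mode)
  compare_clusterings(la, lb, metric = metric)
}

#' Score one graph approximation against the data alone
#'
#' Unsupervised quality: decompose, cluster by segments, and score the
#' induced clustering with an internal clustering-quality index. Useful for
#' hyperparameter tuning when no ground truth is available.
#'
#' @inheritParams compare_graphs_on_data
#' @param graph an [embedded_graph()].
#' @param metric `"silhouette"`, `"calinski_harabasz"` or `"davies_bouldin"`.
#' @return The quality score. A graph inducing a single segment is an error
#'   (the indices are undefined for one cluster).
#' @export
score_graph_on_data <- function(data, graph, metric = "silhouette",
                                mode = c("node", "edge")) {
  mode <- match.arg(mode)
  labels <- cluster_by_segments(data, graph, mode = mode)
  clustering_quality(data, labels, metric = metric)
}
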