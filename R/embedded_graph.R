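#' Embedded graphs
#'
#' An embedded graph is an undirected graph whose nodes carry coordinates in
#' the data space: the basic container for graph-based data approximation.
#' Nodes are indexed `1..n_nodes`; edges are unordered index pairs. Edges are
#' stored canonically (smaller endpoint first, rows sorted), so two graphs
#' with the same edge set compare identical.
#'
#' @param node_coords numeric matrix, one row per node, columns are data-space
#'   coordinates. A vector is treated as a one-column matrix.
#' @param edges two-column integer matrix (or empty) of node index pairs,
#'   1-based. Data frames are accepted.
#' @return An object of class `"embedded_graph"`: a list with elements
#'   `node_coords` and `edges`.
#' @examples
#' g <- embedded_graph(cbind(0:2, 0), rbind(c(1, 2), c(2, 3)))
#' n_nodes(g)
#' graph_degree(g)
#' @seealso [decompose_into_segments()], [read_graph()], [validate_graph()]
#' @export
embedded_graph <- function(node_coords, edges) {
  if (is.null(dim(node_coords))) node_coords <- matrix(node_coords, ncol = 1L)
  node_coords <- as.matrix(node_coords)
  storage.mode(node_coords) <- "double"
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "integer"
    if (ncol(edges) != 2L) stop("'edges' must have two columns")
  }
  g <- structure(list(node_coords = node_coords, edges = edges),
                 class = "embedded_graph")
  validate_graph(g)
}

#' Validate an embedded graph
#'
#' Checks the structural invariants: finite coordinates, edge indices in
#' range, no self-loops, no duplicate (unordered) edges. Violations are
#' errors naming the offending element; duplicate edges are never silently
#' collapsed. Edges are put into canonical order.
#'
#' @param graph an [embedded_graph()].
#' @return The validated graph (edges canonicalized), invisibly classed
#'   `"embedded_graph"`.
#' @export
validate_graph <- function(graph) {
  nc <- graph$node_coords
  ed <- graph$edges
  if (nrow(nc) < 1L) stop("graph must have at least one node")
  if (any(!is.finite(nc))) {
    bad <- which(!is.finite(nc), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite coordinate at node %d, dimension %d",
                 bad[1L], bad[2L]))
  }
  if (nrow(ed) > 0L) {
    if (any(is.na(ed))) stop("edge list contains missing values")
    out <- ed < 1L | ed > nrow(nc)
    if (any(out)) {
      i <- which(rowSums(out) > 0L)[1L]
      stop(sprintf("edge (%d,%d) references a node outside 1..%d",
                   ed[i, 1L], ed[i, 2L], nrow(nc)))
    }
    loop <- ed[, 1L] == ed[, 2L]
    if (any(loop)) {
      i <- which(loop)[1L]
      stop(sprintf("self-loop at node %d", ed[i, 1L]))
    }
    canon <- cbind(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
    key <- paste(canon[, 1L], canon[, 2L])
    if (anyDuplicated(key)) {
      i <- which(duplicated(key))[1L]
      stop(sprintf("duplicate edge (%d,%d)", canon[i, 1L], canon[i, 2L]))
    }
    o <- order(canon[, 1L], canon[, 2L])
    graph$edges <- canon[o, , drop = FALSE]
    storage.mode(graph$edges) <- "integer"
  }
  class(graph) <- unique(c(class(graph), "embedded_graph"))
  graph
}

#' @rdname embedded_graph
#' @export
n_nodes <- function(graph) nrow(graph$node_coords)

#' @rdname embedded_graph
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Node degrees of an embedded graph
#'
#' @param graph an [embedded_graph()].
#' @return Integer vector of length `n_nodes(graph)`.
#' @export
graph_degree <- function(graph) {
  tabulate(c(graph$edges[, 1L], graph$edges[, 2L]), nbins = n_nodes(graph))
}

# adjacency list: for node i, integer vector of neighbours (ascending)
adjacency_list <- function(graph) {
  n <- n_nodes(graph)
  adj <- vector("list", n)
  ed <- graph$edges
  for (i in seq_len(nrow(ed))) {
    a <- ed[i, 1L]; b <- ed[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, function(v) if (is.null(v)) integer(0) else sort.int(v))
}

#' Count branching points
#'
#' A branching node has degree three or more. The count of such nodes is the
#' simplest "naive" metric for judging a tree-shaped approximation against a
#' ground truth whose branch structure is known.
#'
#' @param graph an [embedded_graph()].
#' @return Integer count of nodes with degree >= 3.
#' @export
count_branch_points <- function(graph) {
  sum(graph_degree(graph) >= 3L)
}

#' Branch-point displacement between two graphs
#'
#' For each branching point of `reference`, finds the nearest (Euclidean,
#' in data space) branching point of `graph`. When `graph` has fewer
#' branching points than `reference`, one point may serve as nearest to
#' several; surplus branching points of `graph` are ignored.
#'
#' @param graph the approximating [embedded_graph()].
#' @param reference the ground-truth [embedded_graph()]; must have at least
#'   one branching point.
#' @return List with `matched_count` (number of distinct branch points of
#'   `graph` used) and `mean_distance` (mean over reference branch points of
#'   the matched distance; `Inf` when `graph` has no branching point).
#' @export
branch_point_displacement <- function(graph, reference) {
  ref_bp <- which(graph_degree(reference) >= 3L)
  if (length(ref_bp) == 0L) stop("'reference' has no branching points")
  app_bp <- which(graph_degree(graph) >= 3L)
  if (length(app_bp) == 0L) {
    return(list(matched_count = 0L, mean_distance = Inf))
  }
  d2 <- sq_dist_matrix(reference$node_coords[ref_bp, , drop = FALSE],
                       graph$node_coords[app_bp, , drop = FALSE])
  nearest <- max.col(-d2, ties.method = "first")
  list(matched_count = length(unique(nearest)),
       mean_distance = mean(sqrt(d2[cbind(seq_along(ref_bp), nearest)])))
}

#' Insert a midpoint node into every edge
#'
#' Refines a graph without changing its trajectories: each edge is replaced
#' by a two-edge chain through a new node at the edge midpoint. Segment
#' structure (and hence the induced clustering, up to nearest-node boundary
#' effects) is preserved.
#'
#' @param graph an [embedded_graph()].
#' @return A refined `"embedded_graph"`.
#' @export
subdivide_edges <- function(graph) {
  ed <- graph$edges
  if (nrow(ed) == 0L) return(graph)
  mid <- (graph$node_coords[ed[, 1L], , drop = FALSE] +
            graph$node_coords[ed[, 2L], , drop = FALSE]) / 2
  n0 <- n_nodes(graph)
  new_ids <- n0 + seq_len(nrow(ed))
  embedded_graph(rbind(graph$node_coords, mid),
                 rbind(cbind(ed[, 1L], new_ids), cbind(new_ids, ed[, 2L])))
}

#' @export
print.embedded_graph <- function(x, ...) {
  deg <- graph_degree(x)
  cat(sprintf("Embedded graph: %d nodes in %d dimensions, %d edges\n",
              n_nodes(x), ncol(x$node_coords), n_edges(x)))
  cat(sprintf("  leaves: %d, branching points (deg >= 3): %d\n",
              sum(deg == 1L), sum(deg >= 3L)))
  invisible(x)
}

#' @export
summary.embedded_graph <- function(object, ...) {
  deg <- graph_degree(object)
  seg <- decompose_into_segments(object)
  lens <- if (n_edges(object) > 0L) {
    sqrt(rowSums((object$node_coords[object$edges[, 1L], , drop = FALSE] -
                    object$node_coords[object$edges[, 2L], , drop = FALSE])^2))
  } else numeric(0)
  out <- list(n_nodes = n_nodes(object), n_edges = n_edges(object),
              dim = ncol(object$node_coords),
              n_leaves = sum(deg == 1L), n_branch_points = sum(deg >= 3L),
              n_segments = length(seg$segments),
              total_length = sum(lens), mean_edge_length = mean(lens))
  class(out) <- "summary.embedded_graph"
  out
}

#' @export
print.summary.embedded_graph <- function(x, ...) {
  cat(sprintf("Embedded graph: %d nodes (%d-d), %d edges, %d segments\n",
              x$n_nodes, x$dim, x$n_edges, x$n_segments))
  cat(sprintf("  leaves %d | branch points %d | total length %.4g | mean edge %.4g\n",
              x$n_leaves, x$n_branch_points, x$total_length, x$mean_edge_length))
  invisible(x)
}

#' Plot an embedded graph over its data cloud
#'
#' Projects data and graph onto two dimensions (the leading principal
#' components of the data when the ambient dimension exceeds two) and draws
#' the point cloud with the graph skeleton on top.
#'
#' @param x an [embedded_graph()].
#' @param data optional data matrix to draw beneath the graph; points are
#'   coloured by induced segment label when `col_segments` is `TRUE`.
#' @param col_segments logical; colour data points by nearest segment.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.embedded_graph <- function(x, data = NULL, col_segments = TRUE, ...) {
  nc <- x$node_coords
  if (ncol(nc) > 2L) {
    basis <- if (!is.null(data)) {
      stats::prcomp(data, center = TRUE, scale. = FALSE)
    } else {
      stats::prcomp(nc, center = TRUE, scale. = FALSE)
    }
    proj <- function(m) scale(m, center = basis$center, scale = FALSE) %*%
      basis$rotation[, 1:2, drop = FALSE]
    nc2 <- proj(nc)
    dat2 <- if (!is.null(data)) proj(as_points_matrix(data)) else NULL
  } else {
    nc2 <- nc
    dat2 <- if (!is.null(data)) as_points_matrix(data) else NULL
  }
  if (!is.null(dat2)) {
    cols <- "grey70"
    if (isTRUE(col_segments) && n_edges(x) > 0L) {
      lab <- cluster_by_segments(data, x)
      cols <- grDevices::hcl.colors(max(lab$label), "Dark 3")[lab$label]
    }
    plot(dat2, col = cols, pch = 16, cex = 0.5,
         xlab = "dim 1", ylab = "dim 2", ...)
  } else {
    plot(nc2, type = "n", xlab = "dim 1", ylab = "dim 2", ...)
  }
  if (n_edges(x) > 0L) {
    segments(nc2[x$edges[, 1L], 1L], nc2[x$edges[, 1L], 2L],
             nc2[x$edges[, 2L], 1L], nc2[x$edges[, 2L], 2L], lwd = 2)
  }
  points(nc2, pch = 21, bg = "white", cex = 1.1)
  deg <- graph_degree(x)
  if (any(deg >= 3L)) {
    points(nc2[deg >= 3L, , drop = FALSE], pch = 21, bg = "red", cex = 1.4)
  }
  invisible(x)
}
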