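#' K-means centers for graph-node placement
#'
#' Runs k-means (Hartigan-Wong, several random restarts, best inertia kept)
#' under a fixed seed, returning the centroid matrix. This is the node-
#' placement step of the MST-based approximator.
#'
#' @param data numeric point matrix.
#' @param n_nodes number of clusters K (2 or more, at most the number of
#'   points).
#' @param seed integer seed; the call is deterministic given the seed.
#' @param nstart random restarts (default 10).
#' @return List with `centers` (K x m matrix) and `inertia` (total
#'   within-cluster sum of squares).
#' @export
kmeans_centers <- function(data, n_nodes, seed = 0L, nstart = 10L) {
  x <- as_points_matrix(data)
  if (n_nodes > nrow(x)) {
    stop(sprintf("n_nodes (%d) exceeds the number of points (%d)",
                 n_nodes, nrow(x)))
  }
  if (n_nodes < 1L) stop("n_nodes must be at least 1")
  km <- with_seed(seed, {
    fit <- NULL
    for (attempt in 0:4) {
      fit <- tryCatch(
        stats::kmeans(x, centers = n_nodes, nstart = nstart, iter.max = 100L),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) stop("k-means failed to produce ", n_nodes, " clusters")
    fit
  })
  list(centers = unname(km$centers), inertia = km$tot.withinss)
}

#' k-nearest-neighbour graph over node coordinates
#'
#' Undirected union of each node's k nearest neighbours, weighted by
#' Euclidean distance. `k_neighbors = "all"` yields the complete graph —
#' the recommended default, since the subsequent minimum spanning tree does
#' not depend on k once the graph is dense enough.
#'
#' @param nodes numeric matrix of node coordinates (>= 2 rows).
#' @param k_neighbors positive integer or `"all"`. A finite k of
#'   `n_nodes - 1` or more is clamped with a warning.
#' @return List of class `"weighted_graph"`: `nodes`, `edges` (two-column,
#'   canonical order), `weights`.
#' @export
knn_graph <- function(nodes, k_neighbors = "all") {
  nodes <- as_points_matrix(nodes, "nodes")
  n <- nrow(nodes)
  if (n < 2L) stop("need at least 2 nodes")
  d <- sqrt(sq_dist_matrix(nodes, nodes))
  if (identical(k_neighbors, "all")) {
    idx <- which(upper.tri(d), arr.ind = TRUE)
  } else {
    k <- as.integer(k_neighbors)
    if (k < 1L) stop("k_neighbors must be >= 1 or \"all\"")
    if (k > n - 1L) {
      warning(sprintf("k_neighbors = %d clamped to n_nodes - 1 = %d", k, n - 1L))
      k <- n - 1L
    }
    pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
      nb <- order(d[i, ], seq_len(n))  # self first (distance 0)
      nb <- setdiff(nb, i)[seq_len(k)]
      cbind(pmin(i, nb), pmax(i, nb))
    }))
    idx <- unique(pairs)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  }
  structure(list(nodes = nodes,
                 edges = cbind(idx[, 1L], idx[, 2L]),
                 weights = d[idx]),
            class = "weighted_graph")
}

#' Minimum spanning tree of a weighted graph
#'
#' Kruskal's algorithm with a fully deterministic tie-break: edges are
#' processed in order of (weight, smaller endpoint, larger endpoint), so the
#' returned tree is unique even with tied weights.
#'
#' @param g a [knn_graph()] result (class `"weighted_graph"`).
#' @param forest if `TRUE`, a disconnected input yields a minimum spanning
#'   forest; by default it is an error naming the components.
#' @return An [embedded_graph()] with the input nodes and the tree edges.
#' @export
minimum_spanning_tree <- function(g, forest = FALSE) {
  stopifnot(inherits(g, "weighted_graph"))
  n <- nrow(g$nodes)
  ord <- order(g$weights, g$edges[, 1L], g$edges[, 2L])
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  keep <- integer(0)
  for (e in ord) {
    ra <- find(g$edges[e, 1L]); rb <- find(g$edges[e, 2L])
    if (ra != rb) {
      parent[ra] <- rb
      keep <- c(keep, e)
      if (length(keep) == n - 1L) break
    }
  }
  if (length(keep) < n - 1L && !forest) {
    comp <- vapply(seq_len(n), find, integer(1))
    sizes <- table(comp)
    stop(sprintf("graph is disconnected (%d components, sizes %s); use forest = TRUE for a spanning forest",
                 length(sizes), paste(sizes, collapse = ", ")))
  }
  embedded_graph(g$nodes, g$edges[keep, , drop = FALSE])
}

#' Fit an MST-based tree approximation
#'
#' The simplest widely used graph-based approximator for trajectory-shaped
#' data: place K nodes by k-means, connect them by a k-nearest-neighbour
#' graph (complete by default) weighted by Euclidean distance, and keep its
#' minimum spanning tree. The single important parameter is `n_nodes`; too
#' few nodes cannot express the branching structure, too many "overbranch",
#' creating spurious branch points.
#'
#' @param data numeric point matrix (points x dimensions).
#' @param n_nodes number of graph nodes (= k-means clusters).
#' @param k_neighbors `"all"` (default) or a positive integer.
#' @param seed integer seed controlling the k-means restarts.
#' @return An object of classes `"mst_tree"` and `"embedded_graph"` with
#'   extra fields `inertia`, `params`, and `call`. Standard methods
#'   (`print`, `summary`, `plot`, `predict`) apply.
#' @examples
#' d <- generate_tree_dataset(shape = "binary_tree_7edges", seed = 1)
#' fit <- mst_approximate(d$data, n_nodes = 10, seed = 1)
#' count_branch_points(fit)
#' @export
mst_approximate <- function(data, n_nodes, k_neighbors = "all", seed = 0L) {
  if (n_nodes < 2L) stop("n_nodes must be at least 2")
  km <- kmeans_centers(data, n_nodes, seed = seed)
  g <- knn_graph(km$centers, k_neighbors = k_neighbors)
  tree <- minimum_spanning_tree(g)
  tree$inertia <- km$inertia
  tree$params <- list(n_nodes = n_nodes, k_neighbors = k_neighbors, seed = seed)
  tree$call <- match.call()
  class(tree) <- c("mst_tree", class(tree))
  tree
}

#' @export
print.mst_tree <- function(x, ...) {
  cat("MST-based tree approximation\n")
  cat(sprintf("  n_nodes = %d, k_neighbors = %s, seed = %d, inertia = %.4g\n",
              x$params$n_nodes, as.character(x$params$k_neighbors),
              x$params$seed, x$inertia))
  NextMethod()
}

#' Predict segment membership or projections for new points
#'
#' For a fitted tree (MST-based or elastic), returns per-point quantities
#' derived from the graph: the induced segment label, the nearest node, or
#' the orthogonal projection onto the piecewise-linear tree.
#'
#' @param object an `"embedded_graph"` (including fitted `"mst_tree"` /
#'   `"elastic_tree"` objects).
#' @param newdata numeric point matrix.
#' @param type `"segment"` (induced cluster labels), `"node"` (nearest node
#'   index), or `"projection"` (closest point on the tree; returns a data
#'   frame of edge, offset, distance).
#' @param ... unused.
#' @return See `type`.
#' @export
predict.embedded_graph <- function(object, newdata,
                                   type = c("segment", "node", "projection"),
                                   ...) {
  type <- match.arg(type)
  x <- as_points_matrix(newdata, "newdata")
  switch(type,
         segment = cluster_by_segments(x, object)$label,
         node = assign_nearest_node(x, object)$nearest_node,
         projection = {
           rows <- lapply(seq_len(nrow(x)), function(i)
             as.data.frame(project_point(object, x[i, ])))
           do.call(rbind, rows)
         })
}

#' Residual distances from points to a fitted tree
#'
#' @param object an `"embedded_graph"`.
#' @param newdata numeric point matrix.
#' @param ... unused.
#' @return Numeric vector of Euclidean distances from each point to its
#'   projection on the tree.
#' @export
residuals.embedded_graph <- function(object, newdata, ...) {
  predict(object, newdata, type = "projection")$distance
}
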