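#' Generate a ground-truthed tree-shaped point cloud
#'
#' Samples points along an embedded tree skeleton and adds isotropic
#' Gaussian noise, returning the data together with the ground-truth graph
#' and per-point ground-truth segment labels. This is the generative model
#' used throughout the benchmarks: branching trajectories in a
#' high-dimensional ambient space.
#'
#' Named shapes:
#' * `"binary_tree_7edges"` — a symmetric binary tree: a stem edge followed
#'   by two levels of bifurcation (8 skeleton nodes, 7 edges, 3 branching
#'   points).
#' * `"dumbbell"` — a bar with two short spokes at each end (2 branching
#'   points), a skeletal stand-in for two blobs joined by a bridge.
#'
#' The skeleton is embedded by walking from the root: each edge receives an
#' independent random unit direction in the ambient space, rejected until
#' it keeps at least a 15 degree angle to every other edge ray at the
#' shared node so branches stay distinguishable. Points are placed
#' uniformly along each edge, `points_per_edge` per edge, then perturbed by
#' `N(0, noise_sd^2)` in every ambient coordinate. Ground-truth labels are
#' the segment (of the ground-truth graph's decomposition) that generated
#' each point, so at zero noise the segment-induced clustering of the
#' ground-truth graph reproduces the labels exactly.
#'
#' @param shape a named shape (above) or an [embedded_graph()] used as the
#'   already-embedded skeleton (its coordinates are used as is and
#'   `ambient_dim` / `edge_length` are ignored).
#' @param ambient_dim ambient dimension (default 20).
#' @param noise_sd per-coordinate Gaussian noise standard deviation
#'   (default 5).
#' @param points_per_edge points sampled on each skeleton edge
#'   (default 100).
#' @param edge_length skeleton edge length in data units (default 100;
#'   with the default noise this is the well-separated, low-noise regime).
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return List with `data` (matrix), `ground_truth` ([embedded_graph()]),
#'   `truth_labels` (`"segment_labels"`), and `spec` (the generative
#'   parameters).
#' @examples
#' d <- generate_tree_dataset(shape = "binary_tree_7edges", seed = 1)
#' count_branch_points(d$ground_truth)
#' @export
generate_tree_dataset <- function(shape = "binary_tree_7edges",
                                  ambient_dim = 20L, noise_sd = 5,
                                  points_per_edge = 100L, edge_length = 100,
                                  seed = 0L) {
  stopifnot(ambient_dim >= 2L, points_per_edge >= 1L, noise_sd >= 0)
  if (inherits(shape, "embedded_graph")) {
    skeleton <- validate_graph(shape)
    shape_name <- "custom"
  } else {
    topo <- skeleton_topology(shape)
    skeleton <- with_seed(seed, embed_skeleton(topo, ambient_dim, edge_length))
    shape_name <- shape
  }
  decomp <- decompose_into_segments(skeleton)
  ed <- skeleton$edges
  if (nrow(ed) == 0L) stop("skeleton must have at least one edge")

  sampled <- with_seed(as.integer((as.double(seed) + 104729) %% 2147483647), {
    pts <- vector("list", nrow(ed))
    for (e in seq_len(nrow(ed))) {
      a <- skeleton$node_coords[ed[e, 1L], ]
      b <- skeleton$node_coords[ed[e, 2L], ]
      t <- stats::runif(points_per_edge)
      pts[[e]] <- outer(t, b - a) + rep(a, each = points_per_edge)
    }
    x <- do.call(rbind, pts)
    x + matrix(stats::rnorm(length(x), sd = noise_sd), nrow(x))
  })
  labels <- rep(decomp$edge_to_segment, each = points_per_edge)
  list(data = sampled,
       ground_truth = skeleton,
       truth_labels = structure(list(label = labels,
                                     n_segments = n_segments(decomp)),
                                class = "segment_labels"),
       spec = list(shape = shape_name, ambient_dim = ncol(skeleton$node_coords),
                   noise_sd = noise_sd, points_per_edge = points_per_edge,
                   edge_length = edge_length, seed = seed))
}

# abstract topologies: list(edges, lengths (relative), root)
skeleton_topology <- function(name) {
  switch(name,
         binary_tree_7edges = list(
           edges = rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L), c(3L, 5L),
                         c(3L, 6L), c(4L, 7L), c(4L, 8L)),
           lengths = rep(1, 7), root = 1L),
         dumbbell = list(
           edges = rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(4L, 5L),
                         c(4L, 6L)),
           lengths = c(0.4, 0.4, 1, 0.4, 0.4), root = 1L),
         stop(sprintf("unknown shape '%s'", name)))
}

# Embed an abstract tree: BFS from the root, each edge gets a random unit
# direction kept >= 15 degrees away from the other edge rays at both ends.
embed_skeleton <- function(topo, dim, edge_length) {
  n <- max(topo$edges)
  coords <- matrix(NA_real_, n, dim)
  coords[topo$root, ] <- 0
  rays <- vector("list", n)  # unit rays already incident to each node
  min_cos <- cos(15 * pi / 180)
  adj <- adjacency_from_edges(topo$edges, n)
  elen <- function(a, b) {
    hit <- which((topo$edges[, 1L] == pmin(a, b)) &
                   (topo$edges[, 2L] == pmax(a, b)))
    topo$lengths[hit] * edge_length
  }
  queue <- topo$root
  visited <- logical(n); visited[topo$root] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (visited[w]) next
      repeat {
        dir <- stats::rnorm(dim)
        dir <- dir / sqrt(sum(dir^2))
        ok <- all(vapply(rays[[v]], function(r) sum(r * dir) < min_cos,
                         logical(1)))
        if (ok) break
      }
      coords[w, ] <- coords[v, ] + elen(v, w) * dir
      rays[[v]] <- c(rays[[v]], list(dir))
      rays[[w]] <- c(rays[[w]], list(-dir))
      visited[w] <- TRUE
      queue <- c(queue, w)
    }
  }
  embedded_graph(coords, topo$edges)
}

#' Generate an ensemble of replicate tree datasets
#'
#' Independent replicates of one generative specification, with
#' per-replicate seeds derived deterministically from the ensemble seed, so
#' the whole ensemble is reproducible and replicates are distinct.
#'
#' @inheritParams generate_tree_dataset
#' @param n_replicates number of datasets.
#' @param seed ensemble seed.
#' @return List of [generate_tree_dataset()] results, length
#'   `n_replicates`.
#' @export
replicate_ensemble <- function(n_replicates, shape = "binary_tree_7edges",
                               ambient_dim = 20L, noise_sd = 5,
                               points_per_edge = 100L, edge_length = 100,
                               seed = 0L) {
  stopifnot(n_replicates >= 1L)
  lapply(seq_len(n_replicates), function(i) {
    generate_tree_dataset(shape = shape, ambient_dim = ambient_dim,
                          noise_sd = noise_sd,
                          points_per_edge = points_per_edge,
                          edge_length = edge_length,
                          seed = derive_seed(seed, i - 1L))
  })
}
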