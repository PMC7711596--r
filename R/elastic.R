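#' Elastic principal tree parameters
#'
#' The elastic energy of an embedded tree is the sum of a data-approximation
#' term and two regularizers: `lambda` penalizes squared edge lengths
#' (stretching; keeps edges short and near-equidistant), `mu` penalizes
#' deviation of every star (a node of degree >= 2 with its neighbours) from
#' the harmonic configuration in which the center sits at the mean of its
#' leaves (bending), and `alpha` surcharges the stretching modulus of edges
#' incident to nodes of degree above two, penalizing topological complexity.
#' `r0` is the trimming radius: points farther than `r0` from every node
#' contribute a capped `r0^2` to the data term and exert no pull on the
#' nodes, making the fit robust to outliers.
#'
#' Defaults are the standard choice for trajectory-style data:
#' `lambda = 0.01`, `mu = 0.1`, `alpha = 0.01`, `r0 = Inf`.
#'
#' @param lambda edge-stretching modulus (>= 0).
#' @param mu star-bending modulus (>= 0).
#' @param alpha topological-complexity penalty coefficient (>= 0).
#' @param r0 trimming radius (> 0, possibly `Inf`).
#' @return A list of class `"elastic_params"`.
#' @export
elastic_params <- function(lambda = 0.01, mu = 0.1, alpha = 0.01, r0 = Inf) {
  stopifnot(lambda >= 0, mu >= 0, alpha >= 0, r0 > 0)
  structure(list(lambda = lambda, mu = mu, alpha = alpha, r0 = r0),
            class = "elastic_params")
}

#' Penalized stretching modulus of an edge
#'
#' `lambda + alpha * (max(2, deg(a), deg(b)) - 2)` for an edge with
#' endpoints `a`, `b`: edges touching only nodes of degree at most two pay
#' the plain `lambda`; each extra unit of endpoint degree above two adds
#' `alpha`.
#'
#' @param edge length-2 vector of node indices (must be an edge of `graph`).
#' @param graph an [embedded_graph()].
#' @param params an [elastic_params()] object.
#' @return The penalized modulus (scalar).
#' @export
penalized_lambda <- function(edge, graph, params = elastic_params()) {
  edge <- sort(as.integer(edge))
  hit <- which(graph$edges[, 1L] == edge[1L] & graph$edges[, 2L] == edge[2L])
  if (length(hit) == 0L) {
    stop(sprintf("(%d,%d) is not an edge of the graph", edge[1L], edge[2L]))
  }
  deg <- graph_degree(graph)
  params$lambda + params$alpha * (max(2L, deg[edge[1L]], deg[edge[2L]]) - 2L)
}

# per-edge penalized lambdas, vectorized
edge_lambdas <- function(edges, deg, params) {
  params$lambda + params$alpha *
    (pmax(2L, deg[edges[, 1L]], deg[edges[, 2L]]) - 2L)
}

#' Elastic energy of an embedded graph on a dataset
#'
#' Total energy `U = MSD + UE + UR`:
#' * `msd` — mean over data points of `min(squared distance to the nearest
#'   node, r0^2)`;
#' * `ue` — sum over edges of the penalized stretching modulus times the
#'   squared edge length;
#' * `ur` — `mu` times the sum over stars of the squared distance between
#'   the star center and the mean of its leaves (zero for harmonic stars).
#' Every node of degree two or more forms a star.
#'
#' @param data numeric point matrix.
#' @param graph an [embedded_graph()].
#' @param params an [elastic_params()] object.
#' @return List of class `"energy_breakdown"` with `msd`, `ue`, `ur`,
#'   `total`.
#' @export
elastic_energy <- function(data, graph, params = elastic_params()) {
  x <- as_points_matrix(data)
  if (ncol(x) != ncol(graph$node_coords)) {
    stop("data dimension does not match graph dimension")
  }
  d2 <- sq_dist_matrix(x, graph$node_coords)
  d2min <- d2[cbind(seq_len(nrow(x)), max.col(-d2, ties.method = "first"))]
  energy_terms(d2min, graph$node_coords, graph$edges, params)
}

energy_terms <- function(d2min, coords, edges, params) {
  msd <- mean(pmin(d2min, params$r0^2))
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = nrow(coords))
  ue <- 0
  if (nrow(edges) > 0L) {
    lens2 <- rowSums((coords[edges[, 1L], , drop = FALSE] -
                        coords[edges[, 2L], , drop = FALSE])^2)
    ue <- sum(edge_lambdas(edges, deg, params) * lens2)
  }
  ur <- 0
  stars <- which(deg >= 2L)
  if (length(stars) > 0L && params$mu > 0) {
    adj <- adjacency_from_edges(edges, nrow(coords))
    for (v in stars) {
      m <- colMeans(coords[adj[[v]], , drop = FALSE])
      ur <- ur + sum((coords[v, ] - m)^2)
    }
    ur <- params$mu * ur
  }
  structure(list(msd = msd, ue = ue, ur = ur, total = msd + ue + ur),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("Elastic energy: total %.6g (msd %.6g + ue %.6g + ur %.6g)\n",
              x$total, x$msd, x$ue, x$ur))
  invisible(x)
}

adjacency_from_edges <- function(edges, n) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Optimize node positions at fixed topology
#'
#' Splitting-type (expectation/minimization) descent on the elastic energy:
#' alternate (i) partitioning the data to nearest nodes (points beyond the
#' trimming radius excluded) and (ii) an exact solve of the quadratic
#' minimization for all node positions given the partition (the energy is
#' quadratic in the positions once the partition is fixed, so each
#' half-step is optimal and the total energy never increases). Stops when
#' the relative energy change drops below `relative_tolerance` or after
#' `max_iterations`.
#'
#' @param data numeric point matrix.
#' @param graph an [embedded_graph()] giving the (fixed) topology and the
#'   initial positions.
#' @param params an [elastic_params()] object.
#' @param max_iterations iteration cap (default 100).
#' @param relative_tolerance relative energy-change stopping threshold
#'   (default 1e-5).
#' @return The graph with optimized `node_coords`, plus fields `energy`
#'   (final [elastic_energy()] breakdown), `energy_trace` (total energy per
#'   iteration, non-increasing) and `iterations`.
#' @export
fit_node_positions <- function(data, graph, params = elastic_params(),
                               max_iterations = 100L,
                               relative_tolerance = 1e-5) {
  x <- as_points_matrix(data)
  if (ncol(x) != ncol(graph$node_coords)) {
    stop("data dimension does not match graph dimension")
  }
  res <- elastic_fit_core(x, graph$node_coords, graph$edges, params,
                          max_iterations, relative_tolerance)
  graph$node_coords <- res$coords
  graph$energy <- res$energy
  graph$energy_trace <- res$trace
  graph$iterations <- res$iterations
  graph
}

elastic_fit_core <- function(x, coords, edges, params, max_iter, tol) {
  n_pts <- nrow(x)
  n <- nrow(coords)
  r02 <- params$r0^2
  m_edges <- nrow(edges)

  # topology-dependent pieces, computed once per fit
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = n)
  lam <- if (m_edges > 0L) edge_lambdas(edges, deg, params) else numeric(0)
  W <- NULL  # star rows: center 1, leaves -1/deg
  if (params$mu > 0 && any(deg >= 2L)) {
    stars <- which(deg >= 2L)
    W <- matrix(0, length(stars), n)
    W[cbind(seq_along(stars), stars)] <- 1
    for (e in seq_len(m_edges)) {
      a <- edges[e, 1L]; b <- edges[e, 2L]
      ia <- match(a, stars); ib <- match(b, stars)
      if (!is.na(ia)) W[ia, b] <- -1 / deg[a]
      if (!is.na(ib)) W[ib, a] <- -1 / deg[b]
    }
  }
  A_fix <- matrix(0, n, n)
  if (m_edges > 0L) {
    for (e in seq_len(m_edges)) {
      a <- edges[e, 1L]; b <- edges[e, 2L]; l <- lam[e]
      A_fix[a, a] <- A_fix[a, a] + l; A_fix[b, b] <- A_fix[b, b] + l
      A_fix[a, b] <- A_fix[a, b] - l; A_fix[b, a] <- A_fix[b, a] - l
    }
  }
  if (!is.null(W)) A_fix <- A_fix + params$mu * crossprod(W)

  energy_at <- function(coords, d2min) {
    msd <- mean(pmin(d2min, r02))
    ue <- if (m_edges > 0L) {
      sum(lam * rowSums((coords[edges[, 1L], , drop = FALSE] -
                           coords[edges[, 2L], , drop = FALSE])^2))
    } else 0
    ur <- if (!is.null(W)) params$mu * sum((W %*% coords)^2) else 0
    list(msd = msd, ue = ue, ur = ur, total = msd + ue + ur)
  }

  trace <- numeric(0)
  prev <- Inf
  iter <- 0L
  idx <- seq_len(n_pts)
  repeat {
    d2 <- sq_dist_matrix(x, coords)
    p <- max.col(-d2, ties.method = "first")
    d2min <- d2[cbind(idx, p)]
    en <- energy_at(coords, d2min)
    trace <- c(trace, en$total)
    if (iter >= max_iter) break
    if (is.finite(prev) && prev > 0 && (prev - en$total) / prev < tol) break
    prev <- en$total
    iter <- iter + 1L

    within <- d2min <= r02
    counts <- tabulate(p[within], nbins = n)
    A <- A_fix + diag(counts / n_pts, n)
    B <- matrix(0, n, ncol(x))
    if (any(within)) {
      sums <- rowsum(x[within, , drop = FALSE], p[within])
      B[as.integer(rownames(sums)), ] <- sums / n_pts
    }
    coords <- tryCatch(solve(A, B), error = function(e)
      stop("singular position-update system: no data within the trimming radius and no anchoring elasticity"))
  }
  # final energy at the returned coordinates
  d2 <- sq_dist_matrix(x, coords)
  d2min <- d2[cbind(idx, max.col(-d2, ties.method = "first"))]
  en <- energy_at(coords, d2min)
  structure_en <- structure(en, class = "energy_breakdown")
  list(coords = coords, energy = structure_en, trace = trace,
       iterations = iter)
}

#' Grammar candidates for growing a tree
#'
#' The two topological grammar operations over trees: "add a node to a
#' node" (one candidate per existing node: a new leaf attached to it,
#' placed at the mirror of the node's neighbour mean so the candidate
#' starts in general position) and "bisect an edge" (one candidate per
#' edge: a new degree-2 node at the edge midpoint). All candidates are
#' trees with one more node than the input.
#'
#' @param graph an [embedded_graph()] tree.
#' @return List of candidate `"embedded_graph"`s (length
#'   `n_nodes + n_edges`).
#' @export
grammar_candidates <- function(graph) {
  coords <- graph$node_coords
  edges <- graph$edges
  n <- nrow(coords)
  adj <- adjacency_from_edges(edges, n)
  out <- vector("list", n + nrow(edges))
  # add a node to each node
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    newpos <- if (length(nb) > 0L) {
      2 * coords[v, ] - colMeans(coords[nb, , drop = FALSE])
    } else coords[v, ]
    if (sum((newpos - coords[v, ])^2) < 1e-20) {
      # degenerate mirror: nudge along the first coordinate
      span <- max(apply(coords, 2L, function(z) diff(range(z))), 1)
      newpos <- coords[v, ] + c(1e-3 * span, numeric(ncol(coords) - 1L))
    }
    out[[v]] <- embedded_graph(rbind(coords, newpos),
                               rbind(edges, c(v, n + 1L)))
  }
  # bisect each edge
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    mid <- (coords[a, ] + coords[b, ]) / 2
    new_edges <- rbind(edges[-e, , drop = FALSE],
                       c(a, n + 1L), c(n + 1L, b))
    out[[n + e]] <- embedded_graph(rbind(coords, mid), new_edges)
  }
  out
}

#' Shrink candidates for pruning a tree
#'
#' The inverse grammar operations used by the pruning pass: "remove a leaf"
#' (one candidate per degree-1 node: drop it and its edge) and "collapse an
#' edge" (one candidate per edge: merge its endpoints into a single node at
#' the edge midpoint, inheriting both neighbourhoods). All candidates are
#' trees with one node fewer than the input. Interleaving these with the
#' growth operations is what lets the fit escape a topologically poor
#' initialization — a spurious branch can be retracted, which pure growth
#' can never do.
#'
#' @param graph an [embedded_graph()] tree with at least 3 nodes.
#' @return List of candidate `"embedded_graph"`s.
#' @export
shrink_candidates <- function(graph) {
  coords <- graph$node_coords
  edges <- graph$edges
  n <- nrow(coords)
  if (n < 3L) stop("cannot shrink a tree below 2 nodes")
  deg <- graph_degree(graph)
  out <- list()
  # remove a leaf
  for (v in which(deg == 1L)) {
    keep <- setdiff(seq_len(n), v)
    remap <- integer(n); remap[keep] <- seq_along(keep)
    drop_edge <- edges[, 1L] == v | edges[, 2L] == v
    ed2 <- edges[!drop_edge, , drop = FALSE]
    ed2[] <- remap[ed2]
    out[[length(out) + 1L]] <- embedded_graph(coords[keep, , drop = FALSE], ed2)
  }
  # collapse an edge: endpoints merge at the midpoint
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    keep <- setdiff(seq_len(n), b)
    remap <- integer(n); remap[keep] <- seq_along(keep)
    remap[b] <- remap[a]
    ed2 <- edges[-e, , drop = FALSE]
    ed2[] <- remap[ed2]
    coords2 <- coords[keep, , drop = FALSE]
    coords2[remap[a], ] <- (coords[a, ] + coords[b, ]) / 2
    out[[length(out) + 1L]] <- embedded_graph(coords2, ed2)
  }
  out
}

#' Fit an elastic principal tree
#'
#' Grows a tree node by node: starting from a two-node segment along the
#' first principal component (or from a user-supplied tree such as an MST
#' fit), each step generates all candidate topologies, optimizes every
#' candidate's node positions on the data, and keeps the topology with the
#' minimal elastic energy, until `n_nodes_target` nodes are reached. By
#' default steps are organised in grow/grow/shrink epochs (two
#' [grammar_candidates()] applications followed by one
#' [shrink_candidates()] application, net one node per epoch), mirroring
#' the standard elastic-principal-graph schedule: the shrink pass lets the
#' topology retract spurious branches, so the fit "forgets" even a heavily
#' overbranched initialization within a few steps. With `prune = FALSE`
#' growth is purely additive. The stretching/bending penalties make the
#' resulting trajectories smooth and suppress spurious branching, which is
#' what gives the method its stability over a wide range of node numbers.
#'
#' @param data numeric point matrix.
#' @param n_nodes_target number of nodes to grow to (>= 2, and >= the node
#'   count of `init`).
#' @param params an [elastic_params()] object.
#' @param init `"default"` (two nodes at +/- one standard deviation along
#'   the first principal component) or an [embedded_graph()] tree to start
#'   from.
#' @param max_iterations,relative_tolerance passed to
#'   [fit_node_positions()].
#' @param prune interleave shrink steps with growth (default `TRUE`).
#' @param keep_history if `TRUE`, every accepted intermediate graph is kept
#'   in the history (needed for node-number scans, which read one growth
#'   run at many sizes).
#' @return Object of classes `"elastic_tree"` and `"embedded_graph"`, with
#'   fields `energy`, `params`, `history` (data frame of node count, energy
#'   and branch-point count per accepted step; with `keep_history`, also a
#'   `graphs` attribute, a list of the accepted graphs), and `call`.
#' @examples
#' d <- generate_tree_dataset(shape = "binary_tree_7edges",
#'                            points_per_edge = 15, seed = 1)
#' fit <- grow_tree(d$data, n_nodes_target = 12)
#' count_branch_points(fit)
#' @export
grow_tree <- function(data, n_nodes_target, params = elastic_params(),
                      init = "default", max_iterations = 100L,
                      relative_tolerance = 1e-5, prune = TRUE,
                      keep_history = FALSE) {
  x <- as_points_matrix(data)
  stopifnot(n_nodes_target >= 2L)
  if (identical(init, "default")) {
    pr <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 1L)
    v1 <- pr$rotation[, 1L]
    s <- stats::sd(pr$x[, 1L])
    g <- embedded_graph(rbind(pr$center - s * v1, pr$center + s * v1),
                        matrix(c(1L, 2L), ncol = 2L))
  } else {
    g <- validate_graph(init)
    if (n_edges(g) != n_nodes(g) - 1L) stop("'init' must be a tree")
    if (n_nodes(g) > n_nodes_target) {
      stop("'init' already has more nodes than n_nodes_target")
    }
  }
  g <- fit_node_positions(x, g, params, max_iterations, relative_tolerance)
  hist_rows <- list(data.frame(n_nodes = n_nodes(g), energy = g$energy$total,
                               msd = g$energy$msd,
                               branch_points = count_branch_points(g)))
  graphs <- if (keep_history) list(strip_fit(g)) else NULL

  take_step <- function(g, candidates) {
    best <- NULL
    for (cg in candidates) {
      fit <- fit_node_positions(x, cg, params, max_iterations,
                                relative_tolerance)
      if (is.null(best) || fit$energy$total < best$energy$total) best <- fit
    }
    hist_rows[[length(hist_rows) + 1L]] <<-
      data.frame(n_nodes = n_nodes(best), energy = best$energy$total,
                 msd = best$energy$msd,
                 branch_points = count_branch_points(best))
    if (keep_history) graphs[[length(graphs) + 1L]] <<- strip_fit(best)
    best
  }

  while (n_nodes(g) < n_nodes_target) {
    g <- take_step(g, grammar_candidates(g))
    if (n_nodes(g) < n_nodes_target) g <- take_step(g, grammar_candidates(g))
    if (prune && n_nodes(g) < n_nodes_target && n_nodes(g) >= 3L) {
      g <- take_step(g, shrink_candidates(g))
    }
  }
  g$params <- params
  g$history <- do.call(rbind, hist_rows)
  if (keep_history) attr(g$history, "graphs") <- graphs
  g$call <- match.call()
  class(g) <- unique(c("elastic_tree", class(g)))
  g
}

strip_fit <- function(g) {
  embedded_graph(g$node_coords, g$edges)
}

#' @export
print.elastic_tree <- function(x, ...) {
  cat("Elastic principal tree\n")
  cat(sprintf("  lambda = %g, mu = %g, alpha = %g, r0 = %g\n",
              x$params$lambda, x$params$mu, x$params$alpha, x$params$r0))
  cat(sprintf("  final energy %.6g (msd %.6g)\n",
              x$energy$total, x$energy$msd))
  NextMethod()
}

#' Project a point onto a piecewise-linear tree
#'
#' Finds the closest point of the graph viewed as a piecewise-linear
#' manifold: orthogonal projection onto each edge segment, clamped to its
#' endpoints, minimized over edges (ties broken by the smallest edge
#' index). A projection landing on an endpoint is reported as a node.
#'
#' @param graph an [embedded_graph()].
#' @param x a single point (numeric vector) in the graph's ambient space.
#' @return List with `edge` (edge index, `NA` if the result is a node of an
#'   edgeless graph), `node` (node index if the projection is a node, else
#'   `NA`), `offset` (position along the edge in `[0, 1]`), `distance`.
#' @export
project_point <- function(graph, x) {
  x <- as.numeric(x)
  if (length(x) != ncol(graph$node_coords)) {
    stop("point dimension does not match graph dimension")
  }
  ed <- graph$edges
  if (nrow(ed) == 0L) {
    d <- sqrt(colSums((t(graph$node_coords) - x)^2))
    i <- which.min(d)
    return(list(edge = NA_integer_, node = i, offset = 0, distance = d[i]))
  }
  best <- list(edge = NA_integer_, node = NA_integer_, offset = 0,
               distance = Inf)
  for (e in seq_len(nrow(ed))) {
    a <- graph$node_coords[ed[e, 1L], ]
    b <- graph$node_coords[ed[e, 2L], ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else min(1, max(0, sum((x - a) * ab) / len2))
    d <- sqrt(sum((x - (a + t * ab))^2))
    if (d < best$distance) {
      node <- if (t == 0) ed[e, 1L] else if (t == 1) ed[e, 2L] else NA_integer_
      best <- list(edge = e, node = node, offset = t, distance = d)
    }
  }
  best
}
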