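#' PCA dimensionality reduction
#'
#' Projection onto the top principal components, the standard preprocessing
#' for single-cell expression matrices before graph-based approximation.
#' A deterministic sign convention is applied: each component is flipped so
#' its largest-magnitude loading is positive.
#'
#' @param data numeric point matrix (points x features).
#' @param n_components number of components (at most `min(n, m)`).
#' @return The n x `n_components` score matrix.
#' @export
pca_reduce <- function(data, n_components) {
  x <- as_points_matrix(data)
  if (n_components > min(dim(x))) {
    stop(sprintf("n_components (%d) exceeds min(n, m) = %d",
                 n_components, min(dim(x))))
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  rot <- pr$rotation
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  unname(pr$x %*% diag(flip, ncol(rot)))
}

#' Square-root heuristic for the node number
#'
#' The folklore default for the main parameter of graph-based
#' approximators: take the number of graph nodes as the rounded square root
#' of the number of data points. The benchmarks show it can be far from
#' optimal, which is the motivation for score-based tuning.
#'
#' @param n_points number of data points (>= 1).
#' @return `round(sqrt(n_points))` as an integer.
#' @examples
#' sqrt_heuristic(100)  # 10
#' sqrt_heuristic(447)  # 21
#' @export
sqrt_heuristic <- function(n_points) {
  stopifnot(n_points >= 1)
  as.integer(round(sqrt(n_points)))
}

scan_metric_names <- c("adjusted_rand", "branch_count", "inertia",
                       "silhouette", "calinski_harabasz", "davies_bouldin",
                       "branch_displacement")

#' Node-number scan of an approximator over a replicate ensemble
#'
#' The benchmark workhorse: for every replicate dataset and every node
#' number in `grid`, fit the requested approximator, decompose it, induce
#' the segment clustering, and record supervised scores against the ground
#' truth (adjusted Rand index of the induced clustering versus the truth
#' labels, branch-point count, branch-point displacement) along with
#' unsupervised ones (k-means-style inertia of the node set, silhouette,
#' Calinski-Harabasz, Davies-Bouldin). Elastic trees are grown once per
#' replicate to `max(grid)` with history, so one growth run serves the
#' whole grid.
#'
#' @param ensemble list of datasets from [replicate_ensemble()].
#' @param method `"mst"`, `"elpitree"`, or `"mst_then_elpitree"` (an MST
#'   with `mst_nodes` nodes used to initialize the elastic tree, then grown
#'   along the grid).
#' @param grid strictly increasing integer vector of node numbers.
#' @param metrics subset of metrics to compute (default: all supervised
#'   plus `inertia` and `silhouette`; the other unsupervised indices are
#'   opt-in since they add cost).
#' @param params [elastic_params()] for the elastic methods.
#' @param mst_nodes initializing MST size for `"mst_then_elpitree"`.
#' @param seed base seed for the per-replicate k-means.
#' @return Object of class `"scan_result"`: `method`, `grid`, `scores` (a
#'   list of replicate x grid matrices per metric) and `means` (a data
#'   frame of the column means, one row per grid value). Failed fits are
#'   recorded as `NA`.
#' @export
node_number_scan <- function(ensemble, method = c("mst", "elpitree",
                                                  "mst_then_elpitree"),
                             grid,
                             metrics = c("adjusted_rand", "branch_count",
                                         "inertia", "silhouette",
                                         "branch_displacement"),
                             params = elastic_params(), mst_nodes = 30L,
                             seed = 0L) {
  method <- match.arg(method)
  grid <- as.integer(grid)
  if (any(diff(grid) <= 0L)) stop("grid must be strictly increasing")
  metrics <- match.arg(metrics, scan_metric_names, several.ok = TRUE)
  n_rep <- length(ensemble)
  scores <- lapply(metrics, function(m) matrix(NA_real_, n_rep, length(grid)))
  names(scores) <- metrics

  for (r in seq_len(n_rep)) {
    d <- ensemble[[r]]
    fits <- fit_grid(d$data, method, grid, params, mst_nodes,
                     seed = derive_seed(seed, r))
    for (gi in seq_along(grid)) {
      g <- fits[[gi]]
      if (is.null(g)) next
      row <- tryCatch(
        scan_metrics_for_fit(d, g, metrics),
        error = function(e) NULL)
      if (!is.null(row)) {
        for (m in metrics) scores[[m]][r, gi] <- row[[m]]
      }
    }
  }
  means <- data.frame(n_nodes = grid)
  for (m in metrics) means[[m]] <- colMeans(scores[[m]], na.rm = TRUE)
  structure(list(method = method, grid = grid, scores = scores,
                 means = means),
            class = "scan_result")
}

# fit the approximator at every grid size; returns a list parallel to grid
fit_grid <- function(x, method, grid, params, mst_nodes, seed) {
  if (method == "mst") {
    return(lapply(grid, function(k) {
      tryCatch(mst_approximate(x, n_nodes = k, seed = seed),
               error = function(e) NULL)
    }))
  }
  init <- if (method == "mst_then_elpitree") {
    mst_approximate(x, n_nodes = mst_nodes, seed = seed)
  } else "default"
  fit <- tryCatch(
    grow_tree(x, n_nodes_target = max(grid), params = params, init = init,
              keep_history = TRUE),
    error = function(e) NULL)
  if (is.null(fit)) return(vector("list", length(grid)))
  graphs <- attr(fit$history, "graphs")
  sizes <- fit$history$n_nodes
  lapply(grid, function(k) {
    hit <- which(sizes == k)   # with pruning a size recurs; use the last pass
    if (length(hit) == 0L) NULL else graphs[[hit[length(hit)]]]
  })
}

scan_metrics_for_fit <- function(d, g, metrics) {
  out <- list()
  need_labels <- any(metrics %in% c("adjusted_rand", "silhouette",
                                    "calinski_harabasz", "davies_bouldin"))
  labels <- if (need_labels) cluster_by_segments(d$data, g) else NULL
  for (m in metrics) {
    out[[m]] <- switch(m,
      adjusted_rand = compare_clusterings(labels, d$truth_labels),
      branch_count = as.numeric(count_branch_points(g)),
      inertia = {
        a <- assign_nearest_node(d$data, g)
        sum(a$distance^2)
      },
      silhouette = ,
      calinski_harabasz = ,
      davies_bouldin = tryCatch(clustering_quality(d$data, labels, metric = m),
                                error = function(e) NA_real_),
      branch_displacement =
        branch_point_displacement(g, d$ground_truth)$mean_distance)
  }
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Node-number scan: method '%s', %d replicates, grid %s\n",
              x$method, nrow(x$scores[[1L]]),
              paste(range(x$grid), collapse = "-")))
  print(x$means, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot mean score curves of a scan
#'
#' @param x a [node_number_scan()] result.
#' @param metric which mean curve to draw.
#' @param add add to an existing plot.
#' @param ... passed to [lines()] / [plot()].
#' @return `x`, invisibly.
#' @export
plot.scan_result <- function(x, metric = "adjusted_rand", add = FALSE, ...) {
  y <- x$means[[metric]]
  if (is.null(y)) stop(sprintf("metric '%s' was not computed", metric))
  if (add) {
    graphics::lines(x$grid, y, ...)
  } else {
    plot(x$grid, y, type = "b", xlab = "number of nodes", ylab = metric, ...)
  }
  invisible(x)
}

#' Stability comparison of two node-number scans
#'
#' Quantifies the flatness of each method's mean adjusted-Rand curve: the
#' set of grid values scoring at least 95 percent of the method's peak mean
#' score. A wider near-optimal set means the method is more forgiving of a
#' mis-chosen node number. Also reports mean spurious branch counts (branch
#' count minus the ground truth's) where branch counts were recorded.
#'
#' @param scan_mst,scan_elpi two [node_number_scan()] results on the same
#'   grid and ensemble (conventionally MST and the elastic tree).
#' @param level fraction of the peak defining "near-optimal" (default
#'   0.95).
#' @param truth_branch_points ground-truth branch count used for the
#'   spurious-branch summary (default 3, the symmetric binary tree).
#' @return List of class `"stability_report"` with per-method peak score,
#'   near-optimal grid values, interval width (count of grid values and
#'   node-number span), spurious-branch means, and `wider`, the method
#'   name with the wider near-optimal set.
#' @export
stability_report <- function(scan_mst, scan_elpi, level = 0.95,
                             truth_branch_points = 3L) {
  if (!identical(scan_mst$grid, scan_elpi$grid)) {
    stop("scans use different node-number grids")
  }
  one <- function(scan) {
    ari <- scan$means$adjusted_rand
    if (is.null(ari)) stop("scan lacks the adjusted_rand metric")
    peak <- max(ari, na.rm = TRUE)
    ok <- which(ari >= level * peak)
    spur <- if (!is.null(scan$means$branch_count)) {
      mean(scan$means$branch_count - truth_branch_points)
    } else NA_real_
    list(method = scan$method, peak = peak,
         near_optimal = scan$grid[ok],
         width_count = length(ok),
         width_span = if (length(ok) > 0L) diff(range(scan$grid[ok])) else 0L,
         mean_spurious_branches = spur)
  }
  a <- one(scan_mst); b <- one(scan_elpi)
  wider <- if (b$width_count > a$width_count) b$method
           else if (a$width_count > b$width_count) a$method
           else "tie"
  structure(list(first = a, second = b, level = level, wider = wider),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  for (s in list(x$first, x$second)) {
    cat(sprintf("%s: peak ARI %.3f; >= %.0f%% of peak at %d grid values (span %d nodes): %s\n",
                s$method, s$peak, 100 * x$level, s$width_count,
                s$width_span, paste(s$near_optimal, collapse = ", ")))
    if (!is.na(s$mean_spurious_branches)) {
      cat(sprintf("  mean spurious branch points: %.2f\n",
                  s$mean_spurious_branches))
    }
  }
  cat(sprintf("wider near-optimal range: %s\n", x$wider))
  invisible(x)
}
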