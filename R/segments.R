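#' Decompose a graph into maximal non-branching segments
#'
#' A segment is a path that starts and ends at a branching node (degree >= 3)
#' or a leaf (degree 1) and contains no other branching node. Any graph has a
#' unique partition of its edge set into such segments; this is the object
#' that carries "trajectory" information, as opposed to the raw node/edge
#' structure. Exceptional cases: an isolated cycle (a component with all
#' degrees equal to 2) forms a single segment whose path returns to its start
#' node, and an isolated node forms an edgeless segment of its own. A cycle
#' hanging off a branching node is one segment from that node back to itself.
#'
#' The walk is a depth-first traversal that marks visited *edges* (not just
#' nodes), so cycles are processed correctly. The output is canonically
#' ordered — paths oriented from their smaller-index endpoint, segments
#' sorted by smallest contained node — so the decomposition is deterministic
#' and invariant (up to that canonical order) under node relabelling.
#'
#' @param graph a validated [embedded_graph()].
#' @return An object of class `"segment_decomposition"`: list with
#'   * `segments`: list of integer node paths (for a cycle, first == last;
#'     for an isolated node, a single index),
#'   * `node_to_segments`: per node, the integer vector of segment ids
#'     containing it (a node lies in several segments only if branching),
#'   * `edge_to_segment`: for each row of `graph$edges`, the id of the
#'     segment the edge belongs to.
#' @examples
#' g <- embedded_graph(matrix(rnorm(8), 4), rbind(c(1, 2), c(2, 3), c(2, 4)))
#' decompose_into_segments(g)
#' @export
decompose_into_segments <- function(graph) {
  graph <- validate_graph(graph)
  n <- n_nodes(graph)
  ed <- graph$edges
  m <- nrow(ed)
  deg <- graph_degree(graph)

  # incidence: per node, matrix-free parallel vectors of (neighbour, edge id)
  inc_nb <- vector("list", n)
  inc_id <- vector("list", n)
  for (e in seq_len(m)) {
    a <- ed[e, 1L]; b <- ed[e, 2L]
    inc_nb[[a]] <- c(inc_nb[[a]], b); inc_id[[a]] <- c(inc_id[[a]], e)
    inc_nb[[b]] <- c(inc_nb[[b]], a); inc_id[[b]] <- c(inc_id[[b]], e)
  }
  for (v in seq_len(n)) {
    if (deg[v] > 0L) {
      o <- order(inc_nb[[v]])
      inc_nb[[v]] <- inc_nb[[v]][o]
      inc_id[[v]] <- inc_id[[v]][o]
    }
  }

  used <- logical(m)
  seg_paths <- list()
  seg_edges <- list()

  walk_from <- function(start, first_edge) {
    # follow degree-2 nodes until a branching or leaf node terminates the path
    path <- start
    eids <- integer(0)
    cur <- start
    e <- first_edge
    repeat {
      used[e] <<- TRUE
      eids <- c(eids, e)
      nxt <- if (ed[e, 1L] == cur) ed[e, 2L] else ed[e, 1L]
      path <- c(path, nxt)
      if (deg[nxt] != 2L || nxt == start) break
      nxt_edges <- inc_id[[nxt]]
      e2 <- nxt_edges[!used[nxt_edges]]
      if (length(e2) == 0L) break  # degree-2 cycle closed elsewhere
      e <- e2[1L]
      cur <- nxt
    }
    list(path = path, eids = eids)
  }

  terminals <- which(deg == 1L | deg >= 3L)
  for (s in terminals) {
    for (k in seq_along(inc_id[[s]])) {
      e <- inc_id[[s]][k]
      if (!used[e]) {
        w <- walk_from(s, e)
        seg_paths[[length(seg_paths) + 1L]] <- w$path
        seg_edges[[length(seg_edges) + 1L]] <- w$eids
      }
    }
  }

  # pure cycles: components where every node has degree 2
  if (m > 0L && !all(used)) {
    repeat {
      rem <- which(!used)
      if (length(rem) == 0L) break
      start <- min(ed[rem, ])
      e <- inc_id[[start]][!used[inc_id[[start]]]][1L]
      w <- walk_from(start, e)
      seg_paths[[length(seg_paths) + 1L]] <- w$path
      seg_edges[[length(seg_edges) + 1L]] <- w$eids
    }
  }

  # isolated nodes are degenerate edgeless segments
  for (v in which(deg == 0L)) {
    seg_paths[[length(seg_paths) + 1L]] <- v
    seg_edges[[length(seg_edges) + 1L]] <- integer(0)
  }

  # canonical orientation: paths run from their smaller endpoint; cycles pick
  # the rotationally fixed start (walk start) and the lexicographically
  # smaller direction
  seg_paths <- lapply(seg_paths, function(p) {
    k <- length(p)
    if (k < 2L) return(p)
    if (p[1L] != p[k]) {
      if (p[k] < p[1L]) rev(p) else p
    } else {
      if (k >= 3L && p[k - 1L] < p[2L]) rev(p) else p
    }
  })

  # canonical order: by smallest contained node, then lexicographically
  keys <- vapply(seg_paths,
                 function(p) paste(sprintf("%09d", c(min(p), p)), collapse = ","),
                 character(1))
  o <- order(keys)
  seg_paths <- seg_paths[o]
  seg_edges <- seg_edges[o]

  node_to_segments <- vector("list", n)
  for (si in seq_along(seg_paths)) {
    for (v in unique(seg_paths[[si]])) {
      node_to_segments[[v]] <- c(node_to_segments[[v]], si)
    }
  }
  edge_to_segment <- integer(m)
  for (si in seq_along(seg_edges)) edge_to_segment[seg_edges[[si]]] <- si

  structure(list(segments = seg_paths,
                 node_to_segments = node_to_segments,
                 edge_to_segment = edge_to_segment),
            class = "segment_decomposition")
}

#' @export
print.segment_decomposition <- function(x, ...) {
  cat(sprintf("Segment decomposition: %d segments\n", length(x$segments)))
  show <- utils::head(seq_along(x$segments), 10L)
  for (i in show) {
    p <- x$segments[[i]]
    cat(sprintf("  [%d] %s\n", i, paste(p, collapse = "-")))
  }
  if (length(x$segments) > 10L) {
    cat(sprintf("  ... and %d more\n", length(x$segments) - 10L))
  }
  invisible(x)
}

#' Number of segments in a decomposition
#' @param decomposition a [decompose_into_segments()] result.
#' @return Integer.
#' @export
n_segments <- function(decomposition) length(decomposition$segments)
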