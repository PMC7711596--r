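# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own algorithms.

# Segment oracle: two edges belong to the same segment iff they are linked by
# a chain of shared degree-2 nodes. Components of that edge-adjacency relation
# are the segments (as edge sets); isolated nodes are edgeless segments.
oracle_segment_edge_sets <- function(graph) {
  ed <- graph$edges
  m <- nrow(ed)
  deg <- tabulate(c(ed[, 1L], ed[, 2L]), nbins = nrow(graph$node_coords))
  if (m == 0L) return(list())
  comp <- seq_len(m)
  repeat {
    changed <- FALSE
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      shared <- intersect(ed[i, ], ed[j, ])
      if (length(shared) > 0L && any(deg[shared] == 2L) &&
          comp[i] != comp[j]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(seq_len(m), comp), sort))
}

# canonicalize a decomposition as a sorted list of sorted edge-id sets
decomp_edge_sets <- function(decomposition) {
  m <- length(decomposition$edge_to_segment)
  sets <- split(seq_len(m), decomposition$edge_to_segment)
  unname(lapply(sets, sort))
}

sort_edge_sets <- function(sets) {
  keys <- vapply(sets, function(s) paste(sprintf("%06d", s), collapse = ","),
                 character(1))
  sets[order(keys)]
}

# random Erdos-Renyi embedded graph (coords standard normal)
random_er_graph <- function(n, p, dim = 2L) {
  pairs <- t(combn(n, 2L))
  keep <- runif(nrow(pairs)) < p
  embedded_graph(matrix(rnorm(n * dim), n), pairs[keep, , drop = FALSE])
}

# relabel the nodes of a graph by a permutation perm (new index = perm[old])
permute_graph <- function(graph, perm) {
  coords <- graph$node_coords
  coords[perm, ] <- coords
  ed <- graph$edges
  embedded_graph(coords, cbind(perm[ed[, 1L]], perm[ed[, 2L]]))
}

# brute-force nearest node (double loop, smallest-index ties)
oracle_nearest_node <- function(data, graph) {
  vapply(seq_len(nrow(data)), function(i) {
    d <- apply(graph$node_coords, 1L, function(v) sqrt(sum((data[i, ] - v)^2)))
    which.min(d)
  }, integer(1))
}

# brute-force segment labels: per point, enumerate candidate (segment, node)
# pairs explicitly
oracle_segment_labels <- function(data, graph, decomposition) {
  d2 <- outer(rowSums(data^2), rowSums(graph$node_coords^2), "+") -
    2 * tcrossprod(data, graph$node_coords)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  vapply(seq_len(nrow(data)), function(i) {
    near <- which.min(d[i, ])
    cand <- decomposition$node_to_segments[[near]]
    while (length(cand) > 1L) {
      nodes <- setdiff(unique(unlist(decomposition$segments[cand])), near)
      if (length(nodes) == 0L) return(min(cand))
      nxt <- nodes[order(d[i, nodes], nodes)][1L]
      cand2 <- intersect(decomposition$node_to_segments[[nxt]], cand)
      if (length(cand2) == 1L) return(cand2)
      # recurse: drop the examined node, keep narrowing
      near2 <- nxt
      sub <- cand2
      repeat {
        nodes <- setdiff(unique(unlist(decomposition$segments[sub])),
                         c(near, near2))
        if (length(nodes) == 0L) return(min(sub))
        nxt2 <- nodes[order(d[i, nodes], nodes)][1L]
        sub2 <- intersect(decomposition$node_to_segments[[nxt2]], sub)
        if (length(sub2) == 1L) return(sub2)
        near2 <- c(near2, nxt2)
        sub <- sub2
      }
    }
    cand
  }, integer(1))
}

# exhaustive minimum spanning tree over a complete graph (n <= 7)
oracle_mst_weight <- function(nodes) {
  n <- nrow(nodes)
  pairs <- t(combn(n, 2L))
  w <- sqrt(rowSums((nodes[pairs[, 1L], , drop = FALSE] -
                       nodes[pairs[, 2L], , drop = FALSE])^2))
  best <- Inf
  for (sel in combn(nrow(pairs), n - 1L, simplify = FALSE)) {
    # spanning + acyclic via union-find
    parent <- seq_len(n)
    find <- function(v) { while (parent[v] != v) v <- parent[v]; v }
    ok <- TRUE
    for (e in sel) {
      ra <- find(pairs[e, 1L]); rb <- find(pairs[e, 2L])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (ok) best <- min(best, sum(w[sel]))
  }
  best
}

# a small embedded binary tree (7 edges, 3 branch points) in 2-D
fixture_binary_tree_2d <- function(scale = 1) {
  coords <- scale * rbind(c(0, 0), c(0, 2), c(-2, 3), c(2, 3), c(-3, 5),
                          c(-1, 5), c(1, 5), c(3, 5))
  embedded_graph(coords, rbind(c(1, 2), c(2, 3), c(2, 4), c(3, 5), c(3, 6),
                               c(4, 7), c(4, 8)))
}

# dumbbell fixture: two blobs joined by a bar, with its skeleton graph
fixture_dumbbell <- function(n_blob = 60, n_bar = 30, seed = 42) {
  gbda:::with_seed(seed, {
    blob1 <- cbind(rnorm(n_blob, 0, 1), rnorm(n_blob, 0, 1))
    blob2 <- cbind(rnorm(n_blob, 10, 1), rnorm(n_blob, 0, 1))
    bar <- cbind(runif(n_bar, 0, 10), rnorm(n_bar, 0, 0.2))
    rbind(blob1, blob2, bar)
  })
}
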