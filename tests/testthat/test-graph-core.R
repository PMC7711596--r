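test_that("validation accepts well-formed graphs and names offending elements", {
  g <- embedded_graph(cbind(0:2, 0), rbind(c(1, 2), c(2, 3)))
  expect_s3_class(g, "embedded_graph")
  expect_equal(n_nodes(g), 3L)
  expect_equal(n_edges(g), 2L)

  expect_error(embedded_graph(cbind(0:2, 0), rbind(c(3, 3))), "self-loop")
  expect_error(embedded_graph(cbind(0:2, 0), rbind(c(1, 2), c(2, 1))),
               "duplicate edge")
  expect_error(embedded_graph(cbind(0:2, 0), rbind(c(1, 4))), "outside")
  expect_error(embedded_graph(cbind(c(0, NA, 1), 0), rbind(c(1, 2))),
               "non-finite")
})

test_that("decomposition handles paths, stars, cycles and refinement", {
  path5 <- embedded_graph(cbind(0:4, 0), cbind(1:4, 2:5))
  expect_equal(n_segments(decompose_into_segments(path5)), 1L)
  expect_equal(decompose_into_segments(path5)$segments[[1]], 1:5)

  star <- embedded_graph(rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0)),
                         rbind(c(1, 2), c(1, 3), c(1, 4)))
  dec <- decompose_into_segments(star)
  expect_equal(n_segments(dec), 3L)
  expect_true(all(vapply(dec$segments, length, integer(1)) == 2L))
  # the center belongs to all three segments, leaves to one each
  expect_equal(dec$node_to_segments[[1]], 1:3)
  expect_true(all(lengths(dec$node_to_segments[2:4]) == 1L))

  cyc <- embedded_graph(cbind(cos(1:6), sin(1:6)), cbind(1:6, c(2:6, 1)))
  dec_c <- decompose_into_segments(cyc)
  expect_equal(n_segments(dec_c), 1L)
  p <- dec_c$segments[[1]]
  expect_equal(p[1], p[length(p)])  # cycle closes on itself
  expect_equal(length(p), 7L)

  # binary-tree skeleton: 7 segments, unchanged by bisecting every edge
  bt <- fixture_binary_tree_2d()
  expect_equal(n_segments(decompose_into_segments(bt)), 7L)
  bt2 <- subdivide_edges(bt)
  expect_equal(n_nodes(bt2), 15L)
  expect_equal(n_edges(bt2), 14L)
  expect_equal(n_segments(decompose_into_segments(bt2)), 7L)
})

test_that("degenerate topologies: isolated nodes and lollipop cycles", {
  # two isolated nodes plus one edge -> 3 segments
  g <- embedded_graph(matrix(rnorm(8), 4), rbind(c(1, 2)))
  dec <- decompose_into_segments(g)
  expect_equal(n_segments(dec), 3L)
  expect_equal(sum(lengths(dec$segments) == 1L), 2L)

  # lollipop: triangle 2-3-4 hanging off node 2 which also links to leaf 1
  g <- embedded_graph(matrix(rnorm(8), 4),
                      rbind(c(1, 2), c(2, 3), c(3, 4), c(2, 4)))
  dec <- decompose_into_segments(g)
  expect_equal(n_segments(dec), 2L)
  loop <- dec$segments[[which(vapply(dec$segments, length, integer(1)) == 4L)]]
  expect_equal(loop[1], loop[4])  # cycle starts and ends at the branch node
})

test_that("edge partition, relabelling invariance and oracle agreement on random graphs", {
  set.seed(101)
  for (trial in 1:60) {
    n <- sample(3:12, 1)
    g <- random_er_graph(n, runif(1, 0.1, 0.5))
    dec <- decompose_into_segments(g)
    # every edge in exactly one segment
    if (n_edges(g) > 0L) {
      expect_equal(sort(unlist(decomp_edge_sets(dec))), seq_len(n_edges(g)))
    }
    # consecutive path nodes are joined by edges; interior nodes have degree 2
    deg <- graph_degree(g)
    for (p in dec$segments) {
      if (length(p) < 2L) next
      for (k in seq_len(length(p) - 1L)) {
        a <- min(p[k], p[k + 1L]); b <- max(p[k], p[k + 1L])
        expect_true(any(g$edges[, 1L] == a & g$edges[, 2L] == b))
      }
      interior <- p[-c(1L, length(p))]
      interior <- setdiff(interior, p[1L])  # cycle start can reappear
      expect_true(all(deg[interior] == 2L))
    }
    # nodes in >1 segment must be branching
    multi <- which(lengths(dec$node_to_segments) > 1L)
    expect_true(all(deg[multi] >= 3L))
    # invariance under relabelling: compare segments as sets of node-pair
    # keys, mapping the permuted labels back to the originals
    perm <- sample(n)
    gp <- permute_graph(g, perm)
    dec_p <- decompose_into_segments(gp)
    inv <- integer(n); inv[perm] <- seq_len(n)
    pair_sets <- function(d, graph, relabel = identity) {
      sets <- lapply(decomp_edge_sets(d), function(ids) {
        e <- graph$edges[ids, , drop = FALSE]
        e[] <- relabel(e)
        sort(paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
      })
      sort_keys <- vapply(sets, paste, character(1), collapse = ";")
      sets[order(sort_keys)]
    }
    expect_equal(pair_sets(dec_p, gp, function(v) inv[v]),
                 pair_sets(dec, g))
    # oracle agreement
    expect_equal(sort_edge_sets(decomp_edge_sets(dec)),
                 sort_edge_sets(oracle_segment_edge_sets(g)))
  }
})

test_that("subdivision never changes the segment count", {
  set.seed(7)
  for (trial in 1:20) {
    g <- random_er_graph(sample(3:10, 1), runif(1, 0.15, 0.5))
    n0 <- n_segments(decompose_into_segments(g))
    expect_equal(n_segments(decompose_into_segments(subdivide_edges(g))), n0)
  }
})

test_that("branch point counting and displacement", {
  path <- embedded_graph(cbind(0:3, 0), cbind(1:3, 2:4))
  expect_equal(count_branch_points(path), 0L)
  star <- embedded_graph(rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0)),
                         rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(count_branch_points(star), 1L)
  expect_equal(count_branch_points(fixture_binary_tree_2d()), 3L)

  bt <- fixture_binary_tree_2d()
  self <- branch_point_displacement(bt, bt)
  expect_equal(self$mean_distance, 0)
  expect_equal(self$matched_count, 3L)

  # fewer branch points in the approximation: reuse allowed
  one_bp <- branch_point_displacement(star, bt)
  expect_equal(one_bp$matched_count, 1L)

  # hand-enumerated: ref branch points at (0,0),(10,0); fit at (1,0),(10,1)
  mk_bp <- function(center, id0) {
    coords <- rbind(center, center + c(1, 1), center + c(-1, 1),
                    center + c(0, -1))
    list(coords = coords, edges = cbind(1L, 2:4) + id0)
  }
  build <- function(c1, c2) {
    a <- mk_bp(c1, 0L); b <- mk_bp(c2, 4L)
    embedded_graph(rbind(a$coords, b$coords),
                   rbind(cbind(a$edges[, 1] - 0L, a$edges[, 2]), b$edges))
  }
  ref <- build(c(0, 0), c(10, 0))
  fit <- build(c(1, 0), c(10, 1))
  disp <- branch_point_displacement(fit, ref)
  expect_equal(disp$mean_distance, 1.0)
  expect_equal(disp$matched_count, 2L)

  expect_error(branch_point_displacement(bt, path), "no branching points")
  no_bp <- branch_point_displacement(path, bt)
  expect_identical(no_bp$mean_distance, Inf)
})
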