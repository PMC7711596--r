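test_that("penalized stretching modulus follows the degree surcharge", {
  bt <- fixture_binary_tree_2d()
  p <- elastic_params(lambda = 0.01, alpha = 0.01)
  # edge between leaf (deg 1) and a degree-2 chain would pay plain lambda;
  # here every edge touches a branch node of degree 3 -> lambda + alpha
  expect_equal(penalized_lambda(c(2, 3), bt, p), 0.02)
  path <- embedded_graph(cbind(0:2, 0), cbind(1:2, 2:3))
  expect_equal(penalized_lambda(c(1, 2), path, p), 0.01)
  # degree-4 endpoint: lambda + 2 * alpha
  star4 <- embedded_graph(rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0), c(0, -1)),
                          cbind(1L, 2:5))
  expect_equal(penalized_lambda(c(1, 2), star4, p), 0.03)
  expect_error(penalized_lambda(c(3, 4), bt, p), "not an edge")
})

test_that("energy decomposes into msd + ue + ur with the stated limits", {
  g <- embedded_graph(rbind(c(0, 0), c(3, 0)), rbind(c(1, 2)))
  x <- rbind(c(0, 0), c(3, 0))
  p <- elastic_params(lambda = 1, mu = 0.5, alpha = 0, r0 = Inf)
  en <- elastic_energy(x, g, p)
  expect_equal(en$msd, 0)          # points sit on nodes
  expect_equal(en$ue, 9)           # lambda * d^2
  expect_equal(en$ur, 0)           # no node of degree >= 2
  expect_equal(en$total, en$msd + en$ue + en$ur)

  # harmonic star contributes no bending energy; displaced center does
  star <- embedded_graph(rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1)),
                         rbind(c(1, 2), c(1, 3), c(1, 4)))
  x1 <- matrix(c(0.5, 0.5), 1)
  mu_only <- elastic_params(lambda = 0, mu = 2, alpha = 0)
  en_star <- elastic_energy(x1, star, mu_only)
  # center (0,0) vs leaves mean (0, 1/3): ur = mu * (1/3)^2
  expect_equal(en_star$ur, 2 * (1 / 3)^2)
  harmonic <- star
  harmonic$node_coords[1, ] <- c(0, 1 / 3)
  expect_equal(elastic_energy(x1, harmonic, mu_only)$ur, 0)

  # trimming: far data contributes r0^2 per point and nothing else
  far <- rbind(c(100, 100), c(-50, 80))
  p_trim <- elastic_params(lambda = 1, mu = 0, alpha = 0.7, r0 = 2)
  en_far <- elastic_energy(far, g, p_trim)
  expect_equal(en_far$msd, 4)
  expect_equal(en_far$ue, 9)
  # r0 = Inf reduces msd to the plain mean squared nearest-node distance
  set.seed(4)
  x <- matrix(rnorm(40), 20)
  d2 <- gbda:::sq_dist_matrix(x, g$node_coords)
  expect_equal(elastic_energy(x, g, elastic_params(r0 = Inf))$msd,
               mean(apply(d2, 1, min)))
  # r0 -> 0 limit: msd -> r0^2
  expect_equal(elastic_energy(x, g, elastic_params(r0 = 1e-9))$msd, 1e-18)
})

test_that("position optimization descends monotonically to a stationary point", {
  # single free node with no elasticity = k-means with one center
  set.seed(12)
  x <- matrix(rnorm(60, 5), 30)
  g1 <- embedded_graph(matrix(c(0, 0), 1), NULL)
  fit1 <- fit_node_positions(x, g1, elastic_params(lambda = 0, mu = 0))
  expect_equal(drop(fit1$node_coords), colMeans(x), tolerance = 1e-10)

  # two-node path on mirror-symmetric data keeps the symmetry
  xs <- rbind(x, -x)
  g2 <- embedded_graph(rbind(c(-1, 0), c(1, 0)), rbind(c(1, 2)))
  fit2 <- fit_node_positions(xs, g2)
  expect_equal(fit2$node_coords[1, ], -fit2$node_coords[2, ],
               tolerance = 1e-6)

  # monotone energy descent and finite-difference stationarity on random
  # fixtures
  for (trial in 1:20) {
    n_nodes <- sample(3:8, 1)
    x <- matrix(rnorm(80, sd = 2), 40)
    g <- embedded_graph(matrix(rnorm(2 * n_nodes, sd = 2), n_nodes),
                        cbind(1:(n_nodes - 1), 2:n_nodes))
    p <- elastic_params(lambda = 0.05, mu = 0.1, alpha = 0.01)
    fit <- fit_node_positions(x, g, p, relative_tolerance = 1e-10)
    expect_true(all(diff(fit$energy_trace) <= 1e-9))
    if (trial <= 5) {
      # numeric gradient of the full energy at the optimum is ~ 0
      en_at <- function(coords_vec) {
        gg <- g
        gg$node_coords <- matrix(coords_vec, n_nodes)
        elastic_energy(x, gg, p)$total
      }
      v0 <- as.vector(fit$node_coords)
      grad <- vapply(seq_along(v0), function(k) {
        h <- 1e-5
        vp <- v0; vp[k] <- vp[k] + h
        vm <- v0; vm[k] <- vm[k] - h
        (en_at(vp) - en_at(vm)) / (2 * h)
      }, numeric(1))
      expect_lt(max(abs(grad)), 1e-3)
    }
  }
})

test_that("a huge bending modulus forces stars to harmonic configurations", {
  set.seed(9)
  x <- matrix(rnorm(100, sd = 3), 50)
  star <- embedded_graph(rbind(c(0, 0), c(3, 0), c(-3, 1), c(0, -3)),
                         rbind(c(1, 2), c(1, 3), c(1, 4)))
  fit <- fit_node_positions(x, star, elastic_params(mu = 1e6),
                            relative_tolerance = 1e-12)
  leaves_mean <- colMeans(fit$node_coords[2:4, ])
  expect_equal(fit$node_coords[1, ], leaves_mean, tolerance = 1e-4)
})

test_that("grammar candidates enumerate both operations over all sites", {
  path3 <- embedded_graph(cbind(0:2, 0), cbind(1:2, 2:3))
  expect_length(grammar_candidates(path3), 5L)
  seg <- embedded_graph(cbind(0:1, 0), rbind(c(1, 2)))
  expect_length(grammar_candidates(seg), 3L)
  star <- embedded_graph(rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0)),
                         rbind(c(1, 2), c(1, 3), c(1, 4)))
  cands <- grammar_candidates(star)
  expect_length(cands, 7L)
  for (cg in cands) {
    expect_equal(n_nodes(cg), 5L)
    expect_equal(n_edges(cg), 4L)  # still a tree
  }

  # shrink operations: one per leaf plus one per edge, all trees of n - 1
  shr <- shrink_candidates(star)
  expect_length(shr, 3L + 3L)
  for (cg in shr) {
    expect_equal(n_nodes(cg), 3L)
    expect_equal(n_edges(cg), 2L)
  }
  # collapsing the star's central edge merges the branch point away
  path4 <- embedded_graph(cbind(0:3, 0), cbind(1:3, 2:4))
  shr_p <- shrink_candidates(path4)
  expect_length(shr_p, 2L + 3L)
  expect_error(shrink_candidates(seg), "below 2 nodes")
})

test_that("tree growth respects the node budget and accepts minimal-energy candidates", {
  d <- generate_tree_dataset(points_per_edge = 10, seed = 14)
  fit <- grow_tree(d$data, n_nodes_target = 2)
  expect_equal(n_nodes(fit), 2L)
  expect_equal(count_branch_points(fit), 0L)

  fit8 <- grow_tree(d$data, n_nodes_target = 8, keep_history = TRUE)
  sizes <- fit8$history$n_nodes
  expect_equal(sizes[1], 2L)
  expect_equal(sizes[length(sizes)], 8L)
  expect_true(all(abs(diff(sizes)) == 1L))  # grow/grow/shrink epochs
  expect_equal(n_edges(fit8), 7L)
  # purely additive growth on request
  fit_add <- grow_tree(d$data, n_nodes_target = 6, prune = FALSE,
                       keep_history = TRUE)
  expect_equal(fit_add$history$n_nodes, 2:6)
  # accepted energies: at each step the winner was minimal among candidates,
  # spot-check the last step by refitting all candidates
  graphs <- attr(fit8$history, "graphs")
  prev <- graphs[[length(graphs) - 1L]]
  cands <- grammar_candidates(prev)
  energies <- vapply(cands, function(cg)
    fit_node_positions(d$data, cg)$energy$total, numeric(1))
  expect_equal(fit8$energy$total, min(energies), tolerance = 1e-8)

  # growth from a supplied tree keeps its topology as the starting point
  mst <- mst_approximate(d$data, n_nodes = 6, seed = 1)
  fit_m <- grow_tree(d$data, n_nodes_target = 9, init = mst,
                     keep_history = TRUE)
  expect_equal(fit_m$history$n_nodes[1], 6L)
  expect_equal(n_nodes(fit_m), 9L)
  expect_error(grow_tree(d$data, 4, init = mst), "more nodes")
})

test_that("point projection finds the closest point of the polyline", {
  g <- embedded_graph(rbind(c(0, 0), c(2, 0), c(2, 2)),
                      rbind(c(1, 2), c(2, 3)))
  pr <- project_point(g, c(2, 0))
  expect_equal(pr$node, 2L)
  expect_equal(pr$distance, 0)
  pr_mid <- project_point(g, c(1, -5))
  expect_equal(pr_mid$offset, 0.5)
  expect_equal(pr_mid$edge, 1L)

  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(2, sd = 3)
    pr <- project_point(g, x)
    # dense-sampling oracle along each edge
    ts <- seq(0, 1, length.out = 10001)
    dmin <- min(vapply(seq_len(n_edges(g)), function(e) {
      a <- g$node_coords[g$edges[e, 1], ]; b <- g$node_coords[g$edges[e, 2], ]
      min(sqrt(colSums((t(outer(ts, b - a) + rep(a, each = length(ts))) - x)^2)))
    }, numeric(1)))
    expect_equal(pr$distance, dmin, tolerance = 1e-4)
  }

  # predict()/residuals() expose the same machinery
  d <- matrix(c(1, 1, 3, 1), 2, byrow = TRUE)
  expect_equal(residuals.embedded_graph(g, d), c(1, 1))
  expect_length(predict(g, d, type = "segment"), 2L)
})
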