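test_that("PCA reduction preserves structure with a deterministic sign", {
  set.seed(5)
  # data in a 3-dimensional affine subspace of R^6
  basis <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
  x <- matrix(rnorm(120), 40, 3) %*% t(basis) + rep(1, 40) %o% rnorm(6)
  z <- pca_reduce(x, 3)
  # reconstruction error zero: distances are preserved
  expect_equal(as.vector(dist(z)), as.vector(dist(x)), tolerance = 1e-8)
  # n_components = m preserves total variance exactly
  y <- matrix(rnorm(80), 20, 4)
  zf <- pca_reduce(y, 4)
  expect_equal(sum(apply(zf, 2, var)), sum(apply(y, 2, var)))
  # deterministic under column sign flips of the input's covariance eigenbasis
  expect_identical(pca_reduce(y, 2), pca_reduce(y, 2))
  expect_error(pca_reduce(y, 5), "exceeds")
})

test_that("sqrt heuristic rounds the square root of n", {
  expect_identical(sqrt_heuristic(100), 10L)
  expect_identical(sqrt_heuristic(447), 21L)
  expect_identical(sqrt_heuristic(2), 1L)
  expect_error(sqrt_heuristic(0))
})

test_that("node-number scans aggregate per-replicate scores correctly", {
  ens <- replicate_ensemble(3, points_per_edge = 10, seed = 12)
  grid <- c(4, 8, 12)
  sc <- node_number_scan(ens, "mst", grid,
                         metrics = c("adjusted_rand", "branch_count",
                                     "inertia", "branch_displacement"),
                         seed = 2)
  expect_s3_class(sc, "scan_result")
  expect_equal(dim(sc$scores$adjusted_rand), c(3L, 3L))
  for (m in names(sc$scores)) {
    expect_equal(sc$means[[m]], colMeans(sc$scores[[m]], na.rm = TRUE))
  }
  # deterministic: repeated scan is identical
  sc2 <- node_number_scan(ens, "mst", grid,
                          metrics = c("adjusted_rand", "branch_count",
                                      "inertia", "branch_displacement"),
                          seed = 2)
  expect_identical(sc$scores, sc2$scores)
  expect_error(node_number_scan(ens, "mst", c(8, 4)), "increasing")
})

test_that("elastic scans reuse one growth run across the grid", {
  ens <- replicate_ensemble(2, points_per_edge = 8, seed = 19)
  sc <- node_number_scan(ens, "elpitree", grid = c(4, 6, 8),
                         metrics = c("adjusted_rand", "branch_count"))
  expect_true(all(is.finite(sc$means$adjusted_rand)))
  # MST-initialized variant: grid sizes at and above the initializing MST
  sc_m <- node_number_scan(ens, "mst_then_elpitree", grid = c(6, 8),
                           metrics = c("branch_count"), mst_nodes = 6)
  expect_true(all(is.finite(sc_m$means$branch_count)))
})

test_that("unsupervised scores are near-maximal over the supervised optimum's range", {
  # on the dense binary-tree ensemble the silhouette curve of the MST scan
  # is within 5% of its grid maximum throughout 20-40 nodes, and the best
  # unsupervised grid values fall in that range — the basis for tuning the
  # node number without ground truth
  ens <- replicate_ensemble(5, points_per_edge = 120, edge_length = 170,
                            seed = 21)
  sc <- node_number_scan(ens, "mst", grid = seq(10, 60, 10),
                         metrics = c("silhouette", "davies_bouldin"),
                         seed = 21)
  sil <- sc$means$silhouette
  expect_true(all(sil[2:4] >= 0.95 * max(sil)))
  expect_true(sc$grid[which.max(sil)] %in% c(20, 30, 40))
  # Davies-Bouldin (lower better) flags heavy overbranching clearly
  db <- sc$means$davies_bouldin
  expect_true(all(db[2:4] < db[6]))
})

test_that("stability reports measure the near-optimal plateau width", {
  mk_scan <- function(method, ari) {
    structure(list(method = method, grid = c(5L, 10L, 15L, 20L),
                   scores = list(adjusted_rand = matrix(ari, 1)),
                   means = data.frame(n_nodes = c(5L, 10L, 15L, 20L),
                                      adjusted_rand = ari)),
              class = "scan_result")
  }
  flat <- mk_scan("mst", rep(0.8, 4))
  peaky <- mk_scan("elpitree", c(0.2, 0.9, 0.3, 0.2))
  # identical scans: identical flatness
  rep_same <- stability_report(flat, flat)
  expect_equal(rep_same$first$width_count, rep_same$second$width_count)
  expect_equal(rep_same$wider, "tie")
  # constant curve spans the full grid
  expect_equal(rep_same$first$near_optimal, c(5L, 10L, 15L, 20L))
  rep_mix <- stability_report(peaky, flat)
  expect_equal(rep_mix$wider, "mst")
  expect_equal(rep_mix$first$width_count, 1L)
  bad <- mk_scan("mst", rep(0.5, 4)); bad$grid <- c(1L, 2L, 3L, 4L)
  expect_error(stability_report(flat, bad), "different node-number grids")
})
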