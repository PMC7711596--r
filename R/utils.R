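# internal helpers shared across the package

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a replicate-specific sub-seed that stays inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) + 7919 * as.double(i)) %% 2147483647L)
}

# n_points x n_nodes matrix of squared Euclidean distances.
sq_dist_matrix <- function(points, nodes) {
  pp <- rowSums(points^2)
  nn <- rowSums(nodes^2)
  d2 <- outer(pp, nn, "+") - 2 * tcrossprod(points, nodes)
  d2[d2 < 0] <- 0
  d2
}

as_points_matrix <- function(data, arg = "data") {
  x <- as.matrix(data)
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", arg))
  storage.mode(x) <- "double"
  if (nrow(x) < 1L) stop(sprintf("'%s' must contain at least one point", arg))
  if (any(!is.finite(x))) stop(sprintf("'%s' contains non-finite values", arg))
  x
}
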