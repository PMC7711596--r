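#' Clustering comparison scores
#'
#' Pair-counting and information-theoretic agreement between two labelings
#' of the same points. The "adjusted" scores (adjusted Rand, adjusted mutual
#' information) are chance-corrected: two independent random labelings score
#' near zero, which makes them the recommended defaults for comparing
#' segment-induced clusterings.
#'
#' @param labels_a,labels_b label vectors of equal length, or
#'   `"segment_labels"` objects from [cluster_by_segments()]. Label values
#'   are arbitrary; only the partition matters.
#' @param metric one of `"adjusted_rand"`, `"adjusted_mutual_information"`,
#'   `"fowlkes_mallows"`, `"v_measure"`.
#' @return The score. All four equal 1 for identical partitions (up to label
#'   renaming).
#' @details
#' * `adjusted_rand`: pair-counting Rand index, chance-corrected via the
#'   permutation model on the contingency table margins.
#' * `adjusted_mutual_information`: `(MI - E[MI]) / (mean(H_a, H_b) - E[MI])`
#'   with the expected mutual information under the hypergeometric model and
#'   the arithmetic mean normalizer.
#' * `fowlkes_mallows`: geometric mean of pairwise precision and recall.
#' * `v_measure`: harmonic mean of homogeneity and completeness.
#' @export
compare_clusterings <- function(labels_a, labels_b, metric = "adjusted_rand") {
  a <- extract_labels(labels_a)
  b <- extract_labels(labels_b)
  if (length(a) != length(b)) {
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(a), length(b)))
  }
  ct <- table(a, b)
  out <- switch(match.arg(metric, c("adjusted_rand",
                                    "adjusted_mutual_information",
                                    "fowlkes_mallows", "v_measure")),
                adjusted_rand = ari_from_table(ct),
                adjusted_mutual_information = ami_from_table(ct),
                fowlkes_mallows = fmi_from_table(ct),
                v_measure = v_measure_from_table(ct))
  as.numeric(out)
}

extract_labels <- function(x) {
  if (inherits(x, "segment_labels")) x$label else as.vector(x)
}

choose2 <- function(x) x * (x - 1) / 2

ari_from_table <- function(ct) {
  n <- sum(ct)
  sum_ij <- sum(choose2(ct))
  sum_a <- sum(choose2(rowSums(ct)))
  sum_b <- sum(choose2(colSums(ct)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

fmi_from_table <- function(ct) {
  n <- sum(ct)
  tk <- sum(ct^2) - n
  pk <- sum(rowSums(ct)^2) - n
  qk <- sum(colSums(ct)^2) - n
  if (tk == 0) return(0)
  tk / sqrt(pk * qk)
}

entropy_nats <- function(freq) {
  p <- freq[freq > 0] / sum(freq)
  -sum(p * log(p))
}

mi_from_table <- function(ct) {
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- ct[i, j]
    if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (a[i] * b[j]))
  }
  mi
}

# E[MI] under the hypergeometric (fixed-margins) null model
expected_mi <- function(a, b, n) {
  emi <- 0
  lg <- lgamma
  for (i in seq_along(a)) {
    ai <- a[i]
    for (j in seq_along(b)) {
      bj <- b[j]
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      term <- (nij / n) * log(n * nij / (ai * bj))
      logp <- lg(ai + 1) + lg(bj + 1) + lg(n - ai + 1) + lg(n - bj + 1) -
        lg(n + 1) - lg(nij + 1) - lg(ai - nij + 1) - lg(bj - nij + 1) -
        lg(n - ai - bj + nij + 1)
      emi <- emi + sum(term * exp(logp))
    }
  }
  emi
}

ami_from_table <- function(ct) {
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  ha <- entropy_nats(a); hb <- entropy_nats(b)
  if (ha == 0 && hb == 0) return(1)
  mi <- mi_from_table(ct)
  emi <- expected_mi(a, b, n)
  denom <- (ha + hb) / 2 - emi
  if (denom == 0) return(0)
  (mi - emi) / denom
}

v_measure_from_table <- function(ct) {
  ha <- entropy_nats(rowSums(ct))
  hb <- entropy_nats(colSums(ct))
  if (ha == 0 && hb == 0) return(1)
  mi <- mi_from_table(ct)
  hom <- if (ha == 0) 1 else mi / ha
  com <- if (hb == 0) 1 else mi / hb
  if (hom + com == 0) return(0)
  2 * hom * com / (hom + com)
}

#' Internal clustering quality scores
#'
#' Standard unsupervised indices for a labeling of a point cloud. Silhouette
#' lies in \[-1, 1\] (higher is better), Calinski-Harabasz is positive
#' (higher is better), Davies-Bouldin is non-negative (lower is better). All
#' three favour convex, well-separated clusters, which is also their known
#' limitation on elongated trajectory-shaped clusters.
#'
#' @param data numeric point matrix.
#' @param labels label vector or `"segment_labels"` object; at least two
#'   distinct labels are required.
#' @param metric `"silhouette"`, `"calinski_harabasz"` or `"davies_bouldin"`.
#' @return The score.
#' @export
clustering_quality <- function(data, labels, metric = "silhouette") {
  x <- as_points_matrix(data)
  lab <- extract_labels(labels)
  if (length(lab) != nrow(x)) stop("labels and data differ in length")
  lab <- as.integer(factor(lab))
  k <- max(lab)
  if (k < 2L) stop("clustering quality is undefined for a single cluster")
  switch(match.arg(metric, c("silhouette", "calinski_harabasz",
                             "davies_bouldin")),
         silhouette = {
           sil <- cluster::silhouette(lab, stats::dist(x))
           mean(sil[, "sil_width"])
         },
         calinski_harabasz = calinski_harabasz(x, lab, k),
         davies_bouldin = davies_bouldin(x, lab, k))
}

calinski_harabasz <- function(x, lab, k) {
  n <- nrow(x)
  grand <- colMeans(x)
  centers <- rowsum(x, lab) / as.vector(table(lab))
  sizes <- as.vector(table(lab))
  bgss <- sum(sizes * rowSums(sweep(centers, 2L, grand)^2))
  wgss <- sum((x - centers[lab, , drop = FALSE])^2)
  if (wgss == 0) return(Inf)
  (bgss / (k - 1)) / (wgss / (n - k))
}

davies_bouldin <- function(x, lab, k) {
  centers <- rowsum(x, lab) / as.vector(table(lab))
  # mean distance of members to their centroid
  s <- vapply(seq_len(k), function(i) {
    mean(sqrt(rowSums(sweep(x[lab == i, , drop = FALSE], 2L, centers[i, ])^2)))
  }, numeric(1))
  d <- as.matrix(stats::dist(centers))
  r <- vapply(seq_len(k), function(i) {
    ratios <- (s[i] + s[-i]) / d[i, -i]
    max(ratios[is.finite(ratios)], 0)
  }, numeric(1))
  mean(r)
}
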