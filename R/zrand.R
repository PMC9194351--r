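#' Rand index and z-Rand score between two partitions
#'
#' Compares two community partitions restricted to their common node set.
#' The Rand index is the fraction of node pairs classified consistently
#' (together in both partitions or apart in both). The z-Rand score
#' standardizes `w12`, the number of pairs co-assigned in both partitions,
#' against its exact mean and variance under the null in which one
#' partition's labels are uniformly permuted over the nodes while both
#' partitions' group sizes (and hence their within-group pair counts) stay
#' fixed. The moments are computed in closed form by splitting pairs of
#' node-pairs by how many nodes they share, so the score matches a
#' permutation null exactly rather than approximately.
#'
#' @param p1,p2 Partitions: `community_partition` objects, assignment
#'   tibbles, or named label vectors.
#' @return A one-row tibble with `n` (common nodes), `rand`, `w12`,
#'   `expected_w12`, `sd_w12` and `z_rand` (`NA` with a warning when the
#'   null variance is degenerate).
#' @export
rand_scores <- function(p1, p2) {
  v1 <- as_label_vector(p1)
  v2 <- as_label_vector(p2)
  common <- intersect(names(v1), names(v2))
  if (length(common) < 2L) abort("partitions share fewer than 2 nodes")
  v1 <- v1[common]
  v2 <- v2[common]
  n <- length(common)
  ct <- table(v1, v2)
  g1 <- rowSums(ct)
  g2 <- colSums(ct)
  m <- choose(n, 2)
  m1 <- sum(choose(g1, 2))
  m2 <- sum(choose(g2, 2))
  w12 <- sum(choose(ct, 2))
  rand <- (m + 2 * w12 - m1 - m2) / m
  mu <- m1 * m2 / m
  # second moment: ordered pairs of distinct within-group node pairs,
  # split by whether they share a node (3 distinct nodes) or not (4)
  a1 <- sum(g1 * (g1 - 1) * (g1 - 2)) # share a node, both within-group in p1
  b1 <- m1 * (m1 - 1) - a1 # disjoint
  t2 <- sum(g2 * (g2 - 1) * (g2 - 2))
  f2 <- sum(g2 * (g2 - 1) * (g2 - 2) * (g2 - 3))
  sq <- g2 * (g2 - 1)
  g2x <- sum(sq)^2 - sum(sq^2)
  ew2 <- mu + a1 * t2 / (n * (n - 1) * (n - 2)) +
    b1 * (f2 + g2x) / (n * (n - 1) * (n - 2) * (n - 3))
  v <- ew2 - mu^2
  if (!is.finite(v) || v <= 1e-12) {
    warn("degenerate null variance; z-Rand undefined")
    z <- NA_real_
    sdw <- if (is.finite(v)) sqrt(max(v, 0)) else NA_real_
  } else {
    sdw <- sqrt(v)
    z <- (w12 - mu) / sdw
  }
  tibble(
    n = n, rand = rand, w12 = w12,
    expected_w12 = mu, sd_w12 = sdw, z_rand = z
  )
}

as_label_vector <- function(p) {
  if (inherits(p, "community_partition")) {
    setNames(p$assignment$community, p$assignment$account_id)
  } else if (is.data.frame(p)) {
    setNames(p$community, p$account_id)
  } else {
    if (is.null(names(p))) abort("label vectors must be named by node id")
    p
  }
}
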