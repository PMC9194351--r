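#' Louvain community detection on the symmetrized modularity matrix
#'
#' Greedy multilevel maximization of directed weighted modularity (see
#' [directed_modularity()]) in the GenLouvain style: the full modularity
#' matrix \eqn{B_{ij} = A_{ij} - w_i^{in} w_j^{out} / w} is formed
#' explicitly, symmetrized as \eqn{(B + B^T)/2}, and nodes are greedily
#' moved between communities until no move improves the objective, after
#' which communities are aggregated and the process repeats. The node
#' visitation order is shuffled from `seed`, so results are deterministic
#' given the seed; `n_restarts` independent restarts are run (seeds
#' `seed, seed + 1, ...`) and the best-modularity partition kept.
#'
#' The dense-matrix formulation is faithful to the directed null model but
#' quadratic in the number of nodes; it is intended for networks up to a few
#' thousand nodes.
#'
#' @param net A [retweet_network()].
#' @param seed Integer seed controlling node visitation order.
#' @param resolution Resolution parameter multiplying the null model;
#'   1 is plain modularity.
#' @param n_restarts Number of restarts; the best modularity wins.
#'
#' @return A `community_partition`: an `assignment` tibble
#'   (`account_id`, `community`, dense integer labels ordered by decreasing
#'   community size), the achieved `modularity`, and the `seed` /
#'   `resolution` used.
#' @export
louvain_communities <- function(net, seed = 1L, resolution = 1,
                                n_restarts = 5L) {
  if (net$w <= 0) abort("community detection needs positive total weight")
  bs <- modularity_matrix(net, resolution)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    lab <- withr::with_seed(
      as.integer(seed) + r - 1L,
      louvain_on_matrix(bs)
    )
    q <- sum(bs[outer(lab, lab, "==")]) / net$w
    if (is.null(best) || q > best$q + 1e-12) {
      best <- list(lab = lab, q = q)
    }
  }
  assignment <- tibble(
    account_id = net$nodes$account_id,
    community = relabel_dense(best$lab, net$nodes$account_id)
  )
  structure(
    list(
      assignment = assignment,
      modularity = directed_modularity(net, setNames(
        assignment$community, assignment$account_id
      )),
      seed = as.integer(seed),
      resolution = resolution
    ),
    class = "community_partition"
  )
}

# dense labels 1..k ordered by decreasing size, ties by smallest member id
relabel_dense <- function(lab, ids) {
  sizes <- table(lab)
  firsts <- tapply(ids, lab, min)
  ord <- order(-as.integer(sizes[names(firsts)]), firsts)
  match(as.character(lab), names(firsts)[ord])
}

# one louvain run on a symmetric (generalized) modularity matrix
louvain_on_matrix <- function(bs, tol = 1e-10) {
  n0 <- nrow(bs)
  labels <- seq_len(n0) # node -> current super-node
  repeat {
    n <- nrow(bs)
    comm <- seq_len(n)
    improved_any <- FALSE
    repeat {
      improved <- FALSE
      for (i in sample.int(n)) {
        # contribution of i to each community (off-diagonal terms only)
        row <- bs[i, ]
        row[i] <- 0
        link <- tapply(row, comm, sum)
        cur <- comm[i]
        link_cur <- if (as.character(cur) %in% names(link)) {
          link[[as.character(cur)]]
        } else {
          0
        }
        gain <- link - link_cur
        gain[as.character(cur)] <- 0
        top <- which.max(gain)
        if (gain[[top]] > tol) {
          comm[i] <- as.integer(names(gain)[top])
          improved <- TRUE
          improved_any <- TRUE
        }
      }
      if (!improved) break
    }
    if (!improved_any) break
    # aggregate
    comm <- match(comm, sort(unique(comm)))
    labels <- comm[labels]
    k <- max(comm)
    if (k == n) break
    s <- matrix(0, n, k)
    s[cbind(seq_len(n), comm)] <- 1
    bs <- t(s) %*% bs %*% s
  }
  labels
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf(
    "<community_partition> %d nodes in %d communities, Q = %.4f\n",
    nrow(x$assignment), max(x$assignment$community), x$modularity
  ))
  invisible(x)
}

#' @export
tidy.community_partition <- function(x, ...) x$assignment

#' @export
glance.community_partition <- function(x, ...) {
  tibble(
    modularity = x$modularity,
    n_communities = max(x$assignment$community),
    n_nodes = nrow(x$assignment),
    seed = x$seed,
    resolution = x$resolution
  )
}

#' Community sizes of a partition
#'
#' @param partition A `community_partition` or assignment tibble.
#' @return A tibble with `community` and `size`.
#' @export
community_sizes <- function(partition) {
  assignment <- if (inherits(partition, "community_partition")) {
    partition$assignment
  } else {
    partition
  }
  assignment |> count(.data$community, name = "size")
}
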