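#' Build a weighted directed retweet network
#'
#' Constructs the retweet graph in which the arc from original poster `i` to
#' retweeter `j` carries weight `A_ij`, the number of times account `j`
#' retweeted account `i`. The weighted in-degree of a node is therefore the
#' total number of times it was retweeted, and its weighted out-degree the
#' number of times it retweeted others. Self-retweets are excluded and
#' contribute neither arcs nor nodes.
#'
#' @param tweets A tweet tibble; rows with a non-missing
#'   `retweeted_account_id` different from `account_id` count as retweets.
#' @return A `retweet_network` object holding an `edges` tibble
#'   (`source`, `retweeter`, `weight`), a `nodes` tibble with weighted
#'   in/out strengths, and the total arc weight `w`.
#' @examples
#' tw <- tibble::tibble(
#'   tweet_id = c("1", "2", "3"),
#'   account_id = c("b", "b", "c"),
#'   timestamp = Sys.time() + 0:2,
#'   text = "",
#'   retweeted_account_id = c("a", "a", "a"),
#'   urls = list(character(), character(), character())
#' )
#' retweet_network(tw)
#' @export
retweet_network <- function(tweets) {
  rts <- tweets[
    !is.na(tweets$retweeted_account_id) &
      tweets$retweeted_account_id != tweets$account_id, ,
    drop = FALSE
  ]
  edges <- rts |>
    count(
      source = .data$retweeted_account_id,
      retweeter = .data$account_id,
      name = "weight"
    ) |>
    arrange(.data$source, .data$retweeter)
  new_retweet_network(edges)
}

new_retweet_network <- function(edges) {
  nodes <- sort(unique(c(edges$source, edges$retweeter)))
  in_str <- tapply(edges$weight, edges$source, sum)
  out_str <- tapply(edges$weight, edges$retweeter, sum)
  nodes_tbl <- tibble(
    account_id = nodes,
    in_strength = as.numeric(ifelse(
      is.na(in_str[nodes]), 0, in_str[nodes]
    )),
    out_strength = as.numeric(ifelse(
      is.na(out_str[nodes]), 0, out_str[nodes]
    ))
  )
  structure(
    list(edges = as_tibble(edges), nodes = nodes_tbl, w = sum(edges$weight)),
    class = "retweet_network"
  )
}

#' @export
print.retweet_network <- function(x, ...) {
  cat(sprintf(
    "<retweet_network> %d nodes, %d arcs, total weight %g\n",
    nrow(x$nodes), nrow(x$edges), x$w
  ))
  invisible(x)
}

#' @export
tidy.retweet_network <- function(x, ...) x$edges

#' @export
glance.retweet_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_arcs = nrow(x$edges), total_weight = x$w)
}

#' Largest weakly connected component
#'
#' Restricts a retweet network to its largest weakly connected component (a
#' retweet in either direction connects two accounts). Retweet graphs are
#' close to directed acyclic, so strong components would be tiny and
#' uninformative. Ties in component size are broken toward the component
#' whose sorted node ids come first lexicographically.
#'
#' @param net A [retweet_network()].
#' @return A `retweet_network` induced on the winning component.
#' @export
largest_component <- function(net) {
  if (nrow(net$nodes) == 0L) abort("cannot take the component of an empty network")
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "retweeter")],
    directed = TRUE,
    vertices = net$nodes$account_id
  )
  comp <- igraph::components(g, mode = "weak")
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    firsts <- vapply(
      cand,
      function(k) min(net$nodes$account_id[comp$membership == k]),
      character(1)
    )
    cand <- cand[order(firsts)][1]
  }
  keep <- net$nodes$account_id[comp$membership == cand]
  edges <- net$edges[
    net$edges$source %in% keep & net$edges$retweeter %in% keep, ,
    drop = FALSE
  ]
  out <- new_retweet_network(edges)
  # isolated nodes can only occur in a 1-node component
  if (nrow(out$nodes) == 0L && length(keep) == 1L) {
    out$nodes <- tibble(
      account_id = keep, in_strength = 0, out_strength = 0
    )
  }
  out
}

partition_vector <- function(net, partition) {
  assign <- if (inherits(partition, "community_partition")) {
    setNames(partition$assignment$community, partition$assignment$account_id)
  } else if (is.data.frame(partition)) {
    setNames(partition$community, partition$account_id)
  } else {
    partition
  }
  missing <- setdiff(net$nodes$account_id, names(assign))
  if (length(missing)) {
    abort(sprintf(
      "partition is missing %d node(s), e.g. '%s'",
      length(missing), missing[1]
    ))
  }
  assign[net$nodes$account_id]
}

#' Directed weighted modularity
#'
#' Evaluates the directed, weighted modularity
#' \deqn{Q = \frac{1}{w}\sum_{i}\sum_{j}\left(A_{ij} -
#'   \frac{w_i^{in} w_j^{out}}{w}\right)\delta(C_i, C_j),}
#' where \eqn{w} is the total arc weight, \eqn{w_k^{in}} the number of times
#' account \eqn{k} was retweeted and \eqn{w_k^{out}} the number of times it
#' retweeted others. Diagonal null-model terms (`i == j`) are included even
#' though the graph has no self-loops.
#'
#' @param net A [retweet_network()].
#' @param partition A [louvain_communities()] result, a tibble with
#'   `account_id`/`community` columns, or a named vector of community
#'   labels covering every node.
#' @return The modularity value `Q`.
#' @export
directed_modularity <- function(net, partition) {
  if (net$w <= 0) abort("modularity needs positive total weight")
  comm <- partition_vector(net, partition)
  edge_comm_src <- comm[net$edges$source]
  edge_comm_dst <- comm[net$edges$retweeter]
  internal <- sum(net$edges$weight[edge_comm_src == edge_comm_dst])
  null <- sum(tapply(net$nodes$in_strength, comm, sum) *
    tapply(net$nodes$out_strength, comm, sum))
  internal / net$w - null / net$w^2
}

modularity_matrix <- function(net, resolution = 1) {
  ids <- net$nodes$account_id
  n <- length(ids)
  a <- matrix(0, n, n, dimnames = list(ids, ids))
  a[cbind(
    match(net$edges$source, ids),
    match(net$edges$retweeter, ids)
  )] <- net$edges$weight
  b <- a - resolution *
    outer(net$nodes$in_strength, net$nodes$out_strength) / net$w
  (b + t(b)) / 2
}
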