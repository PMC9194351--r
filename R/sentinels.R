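#' Select sentinel accounts from each community
#'
#' From every sufficiently large community, picks the `k` most frequently
#' retweeted accounts (largest weighted in-degree) as sentinel nodes to be
#' monitored longitudinally. Ties in in-degree are broken toward the
#' lexicographically smaller account id. Communities can additionally be
#' screened with an injectable predicate, standing in for
#' language/geography screening steps that require external services.
#'
#' @param net A [retweet_network()].
#' @param partition A community partition of `net` (see
#'   [louvain_communities()]).
#' @param k Number of sentinels per community (default 15).
#' @param min_size Minimum community size to be considered (default 1).
#' @param community_filter Optional predicate
#'   `function(community, account_ids)` returning `TRUE` to keep the
#'   community. Default keeps everything.
#'
#' @return A tibble with `community`, `rank`, `account_id` and
#'   `in_strength`, sorted by community then rank.
#' @export
select_sentinels <- function(net, partition, k = 15L, min_size = 1L,
                             community_filter = NULL) {
  if (k < 1L) abort("k must be at least 1")
  comm <- partition_vector(net, partition)
  tbl <- net$nodes |>
    mutate(community = as.integer(comm[.data$account_id]))
  sizes <- tbl |> count(.data$community, name = "size")
  keep <- sizes$community[sizes$size >= min_size]
  if (!is.null(community_filter)) {
    keep <- keep[vapply(
      keep,
      function(cc) isTRUE(community_filter(
        cc, tbl$account_id[tbl$community == cc]
      )),
      logical(1)
    )]
  }
  tbl |>
    filter(.data$community %in% keep) |>
    arrange(.data$community, desc(.data$in_strength), .data$account_id) |>
    group_by(.data$community) |>
    slice_head(n = k) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    select("community", "rank", "account_id", "in_strength")
}

#' In-degree coverage of top-k accounts per community
#'
#' For each community, the fraction of all retweets received by community
#' members that are accounted for by its `k` most retweeted accounts. A
#' heavy-tailed in-degree distribution makes this fraction large even for
#' small `k`, which is what justifies monitoring a handful of sentinels per
#' community.
#'
#' @inheritParams select_sentinels
#' @return A `sentinel_coverage` object: a per-community tibble
#'   (`community`, `size`, `total_in`, `topk_in`, `coverage`; `coverage` is
#'   `NA` where the community receives no retweets) with summary statistics
#'   available through `glance()`.
#' @export
sentinel_coverage <- function(net, partition, k = 15L) {
  comm <- partition_vector(net, partition)
  tbl <- net$nodes |>
    mutate(community = as.integer(comm[.data$account_id])) |>
    arrange(.data$community, desc(.data$in_strength), .data$account_id) |>
    group_by(.data$community) |>
    summarise(
      size = n(),
      total_in = sum(.data$in_strength),
      topk_in = sum(head(.data$in_strength, k)),
      .groups = "drop"
    ) |>
    mutate(coverage = if_else(
      .data$total_in > 0, .data$topk_in / .data$total_in, NA_real_
    ))
  structure(
    list(communities = tbl, k = as.integer(k)),
    class = "sentinel_coverage"
  )
}

#' @export
print.sentinel_coverage <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<sentinel_coverage> k = %d: mean %.3f, median %.3f (IQR %.3f-%.3f)\n",
    x$k, g$mean_coverage, g$median_coverage, g$q25, g$q75
  ))
  invisible(x)
}

#' @export
tidy.sentinel_coverage <- function(x, ...) x$communities

#' @export
glance.sentinel_coverage <- function(x, ...) {
  cv <- x$communities$coverage
  tibble(
    k = x$k,
    n_communities = nrow(x$communities),
    mean_coverage = mean(cv, na.rm = TRUE),
    median_coverage = median(cv, na.rm = TRUE),
    q25 = as.numeric(quantile(cv, 0.25, na.rm = TRUE)),
    q75 = as.numeric(quantile(cv, 0.75, na.rm = TRUE))
  )
}
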