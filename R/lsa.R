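#' Topical tweets of a flagged day via latent semantic analysis
#'
#' Identifies the tweets that dominate the day's content by truncated SVD
#' of the tweet-by-trigram count matrix. For each of the `n_components`
#' leading document (left) singular vectors, the absolute component
#' magnitudes are sorted descending and a "sharp drop" is located as the
#' largest ratio between consecutive magnitudes (searched over the top
#' `min(max_positions, n)` positions); tweets above the drop are selected.
#' The result is the union across components, each tweet tagged with the
#' component and magnitude that selected it. Signs of singular vectors are
#' arbitrary and only magnitudes are used. Tweets that clean to an empty
#' trigram vector are excluded before the SVD.
#'
#' @param tweets Tweet tibble for one cluster on one day.
#' @param n_components Number of leading singular vectors (default 5);
#'   reduced with a warning when the matrix rank is lower.
#' @param max_positions Search depth for the drop (default 50).
#' @param stopwords Passed to [clean_text()].
#' @return A tibble with `tweet_id`, `component`, `magnitude` (the best
#'   component per tweet), sorted by magnitude descending.
#' @export
lsa_topical_tweets <- function(tweets, n_components = 5L,
                               max_positions = 50L,
                               stopwords = default_stopwords()) {
  tokens <- clean_text(tweets$text, stopwords)
  vecs <- lapply(tokens, function(tt) trigram_vector(list(tt)))
  keep <- vapply(vecs, length, integer(1)) > 0L
  if (sum(keep) < 2L) {
    abort("need at least 2 tweets with nonempty trigram vectors")
  }
  ids <- tweets$tweet_id[keep]
  vecs <- vecs[keep]
  terms <- sort(unique(unlist(lapply(vecs, names))))
  m <- matrix(0, nrow = length(vecs), ncol = length(terms))
  for (i in seq_along(vecs)) {
    m[i, match(names(vecs[[i]]), terms)] <- vecs[[i]]
  }
  sv <- svd(m)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  k <- min(n_components, rank)
  if (k < n_components) {
    warn(sprintf(
      "matrix rank %d below %d requested components; using %d",
      rank, n_components, k
    ))
  }
  picks <- purrr::map_dfr(seq_len(k), function(comp) {
    mag <- abs(sv$u[, comp])
    ord <- order(mag, decreasing = TRUE)
    sorted <- mag[ord]
    depth <- min(max_positions, length(sorted))
    if (depth < 2L) {
      cut_at <- 1L
    } else {
      ratios <- sorted[1:(depth - 1)] / pmax(sorted[2:depth], 1e-300)
      cut_at <- which.max(ratios)
    }
    tibble(
      tweet_id = ids[ord[seq_len(cut_at)]],
      component = comp,
      magnitude = sorted[seq_len(cut_at)]
    )
  })
  picks |>
    group_by(.data$tweet_id) |>
    arrange(desc(.data$magnitude), .by_group = TRUE) |>
    slice_head(n = 1L) |>
    ungroup() |>
    arrange(desc(.data$magnitude))
}

#' Attribute a burst to cross-cluster topical tweets
#'
#' Verifies whether a flagged day's similarity burst was driven by
#' identifiable content spreading between the two clusters. Topical tweets
#' are extracted per cluster with [lsa_topical_tweets()]; tweets "common
#' to both clusters" are formalized as near-duplicate pairs across the two
#' topical sets (trigram Jaccard at least `match_threshold`). The matched
#' tweets are removed from both clusters' documents for that day, the
#' inter-cluster similarity and burst score are recomputed against the
#' unchanged history, and the flag is marked *attributed* when the
#' recomputed score falls below the flagging threshold.
#'
#' @param flag One row of a `burst_flags` tibble ([flag_bursts()]).
#' @param tweets The full tweet tibble the documents were built from
#'   (already topic-filtered as for [daily_documents()]).
#' @param membership Tibble mapping `account_id` to `community`.
#' @param clusters Tibble mapping `community` to `cluster`.
#' @param series The `similarity_series` the flag came from.
#' @param window The [observation_window()] used throughout.
#' @param threshold,burn_in,sd_type As in [flag_bursts()].
#' @param match_threshold Jaccard threshold for cross-cluster tweet
#'   matching (default 0.5).
#' @param n_components Passed to [lsa_topical_tweets()].
#' @param stopwords Passed to [clean_text()].
#' @return A one-row tibble: the flag plus `topical_a`, `topical_b`,
#'   `removed_a`, `removed_b` (list columns of tweet ids), `new_similarity`,
#'   `new_burst` and `attributed`. With no cross-cluster matches nothing is
#'   removed and the flag is `"unattributed"` (`attributed = FALSE`).
#' @export
attribute_burst <- function(flag, tweets, membership, clusters, series,
                            window, threshold = 2, burn_in = 7L,
                            sd_type = "sample", match_threshold = 0.5,
                            n_components = 5L,
                            stopwords = default_stopwords()) {
  stopifnot(nrow(flag) == 1L)
  clusters <- as_tibble(clusters)
  day_tweets <- tweets |>
    inner_join(membership, by = "account_id") |>
    inner_join(clusters[, c("community", "cluster")], by = "community") |>
    mutate(day = tweet_day(.data$timestamp, window)) |>
    filter(.data$day == flag$day)
  topical <- lapply(c(flag$cluster_a, flag$cluster_b), function(cl) {
    sub <- day_tweets |> filter(.data$cluster == cl)
    if (nrow(sub) < 2L) {
      return(tibble(
        tweet_id = character(), component = integer(),
        magnitude = numeric()
      ))
    }
    lsa_topical_tweets(sub, n_components, stopwords = stopwords)
  })
  # cross-cluster near-duplicate matching on trigram supports
  vec_for <- function(ids) {
    sub <- day_tweets[match(ids, day_tweets$tweet_id), , drop = FALSE]
    toks <- clean_text(sub$text, stopwords)
    lapply(toks, function(tt) trigram_vector(list(tt)))
  }
  va <- vec_for(topical[[1]]$tweet_id)
  vb <- vec_for(topical[[2]]$tweet_id)
  matched_a <- character()
  matched_b <- character()
  if (length(va) && length(vb)) {
    for (i in seq_along(va)) {
      for (j in seq_along(vb)) {
        if (trigram_jaccard(va[[i]], vb[[j]]) >= match_threshold) {
          matched_a <- c(matched_a, topical[[1]]$tweet_id[i])
          matched_b <- c(matched_b, topical[[2]]$tweet_id[j])
        }
      }
    }
  }
  matched_a <- unique(matched_a)
  matched_b <- unique(matched_b)
  removed <- c(matched_a, matched_b)
  if (length(removed)) {
    pruned <- tweets |> filter(!.data$tweet_id %in% removed)
  } else {
    pruned <- tweets
  }
  # recompute the day's similarity for this pair against unchanged history
  day_window <- observation_window(flag$day, flag$day, tz = window$tz)
  docs_day <- daily_documents(pruned, membership, day_window, stopwords)
  sim_day <- cluster_similarity(docs_day, clusters)
  new_sim <- sim_day$similarity[
    sim_day$cluster_a == flag$cluster_a & sim_day$cluster_b == flag$cluster_b
  ]
  hist <- series |>
    filter(
      .data$cluster_a == flag$cluster_a,
      .data$cluster_b == flag$cluster_b,
      .data$day < flag$day,
      !is.na(.data$similarity)
    ) |>
    pull("similarity")
  s <- sd(hist)
  if (sd_type == "population") s <- s * sqrt((length(hist) - 1) / length(hist))
  new_burst <- if (length(hist) >= max(burn_in, 2L) && is.finite(s) && s > 0) {
    (new_sim - mean(hist)) / s
  } else {
    NA_real_
  }
  flag |>
    mutate(
      topical_a = list(topical[[1]]$tweet_id),
      topical_b = list(topical[[2]]$tweet_id),
      removed_a = list(matched_a),
      removed_b = list(matched_b),
      new_similarity = new_sim,
      new_burst = new_burst,
      attributed = length(removed) > 0 && !is.na(new_burst) &&
        new_burst < threshold
    )
}
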