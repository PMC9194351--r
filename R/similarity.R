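#' Daily per-community trigram documents
#'
#' Builds, for every community and every day of the window, the "document"
#' consisting of all of that community's topical tweets sent that day:
#' texts are cleaned ([clean_text()]) and folded into a trigram count
#' vector ([trigram_vector()]). Days on which a community posts nothing
#' yield explicit empty documents, so downstream similarity always sees a
#' complete community-by-day grid.
#'
#' @param tweets A tweet tibble (pre-filter with [match_topic()] to
#'   restrict to, e.g., COVID tweets).
#' @param membership Tibble mapping `account_id` to `community`.
#' @param window An [observation_window()].
#' @param stopwords Passed to [clean_text()].
#' @return A `daily_documents` tibble: `community`, `day`, `n_tweets`,
#'   `tweet_ids` (list), `trigrams` (list of named count vectors).
#' @export
daily_documents <- function(tweets, membership, window,
                            stopwords = default_stopwords()) {
  tw <- tweets |>
    inner_join(membership, by = "account_id") |>
    mutate(day = tweet_day(.data$timestamp, window)) |>
    filter(.data$day >= window$start_day, .data$day <= window$end_day)
  tw$tokens <- clean_text(tw$text, stopwords)
  grid <- tidyr::expand_grid(
    community = sort(unique(membership$community)),
    day = window_days(window)
  )
  docs <- tw |>
    group_by(.data$community, .data$day) |>
    summarise(
      n_tweets = n(),
      tweet_ids = list(.data$tweet_id),
      trigrams = list(trigram_vector(.data$tokens)),
      .groups = "drop"
    )
  out <- grid |>
    left_join(docs, by = c("community", "day")) |>
    mutate(
      n_tweets = ifelse(is.na(.data$n_tweets), 0L, .data$n_tweets),
      tweet_ids = purrr::map(.data$tweet_ids, ~ .x %||% character()),
      trigrams = purrr::map(
        .data$trigrams, ~ .x %||% setNames(numeric(), character())
      )
    )
  class(out) <- c("daily_documents", class(out))
  out
}

#' Daily inter-cluster similarity series
#'
#' For every day and every unordered pair of community clusters, the
#' similarity `s_t(A, B)` is the arithmetic mean of the trigram cosine
#' similarities over all community pairs `(a in A, b in B)`. Pairs
#' involving an empty document contribute similarity 0 and stay in the
#' mean (their count is reported in `n_empty`). Setting
#' `include_within = TRUE` adds the within-cluster diagnostic series
#' (`A == B`, distinct unordered community pairs).
#'
#' @param docs A [daily_documents()] tibble.
#' @param clusters Tibble mapping `community` to `cluster` (e.g.
#'   `tidy(cluster_scores(...))`).
#' @param include_within Also compute within-cluster series.
#' @return A `similarity_series` tibble: `day`, `cluster_a`, `cluster_b`,
#'   `similarity`, `n_pairs`, `n_empty`.
#' @export
cluster_similarity <- function(docs, clusters, include_within = FALSE) {
  clusters <- as_tibble(clusters)
  docs <- docs |>
    inner_join(clusters[, c("community", "cluster")], by = "community")
  labs <- sort(unique(clusters$cluster))
  pairs <- tidyr::expand_grid(cluster_a = labs, cluster_b = labs) |>
    filter(if (include_within) {
      .data$cluster_a <= .data$cluster_b
    } else {
      .data$cluster_a < .data$cluster_b
    })
  days <- sort(unique(docs$day))
  out <- purrr::map_dfr(days, function(d) {
    dd <- docs[docs$day == d, , drop = FALSE]
    purrr::map_dfr(seq_len(nrow(pairs)), function(p) {
      a <- dd[dd$cluster == pairs$cluster_a[p], , drop = FALSE]
      b <- dd[dd$cluster == pairs$cluster_b[p], , drop = FALSE]
      within <- pairs$cluster_a[p] == pairs$cluster_b[p]
      if (nrow(a) == 0L || nrow(b) == 0L ||
        (within && nrow(a) < 2L)) {
        return(tibble(
          day = d, cluster_a = pairs$cluster_a[p],
          cluster_b = pairs$cluster_b[p],
          similarity = NA_real_, n_pairs = 0L, n_empty = 0L
        ))
      }
      idx <- if (within) {
        utils::combn(seq_len(nrow(a)), 2)
      } else {
        rbind(
          rep(seq_len(nrow(a)), times = nrow(b)),
          rep(seq_len(nrow(b)), each = nrow(a))
        )
      }
      sims <- vapply(seq_len(ncol(idx)), function(k) {
        cosine_similarity(
          a$trigrams[[idx[1, k]]], b$trigrams[[idx[2, k]]]
        )
      }, numeric(1))
      empty <- vapply(seq_len(ncol(idx)), function(k) {
        length(a$trigrams[[idx[1, k]]]) == 0L ||
          length(b$trigrams[[idx[2, k]]]) == 0L
      }, logical(1))
      tibble(
        day = d, cluster_a = pairs$cluster_a[p],
        cluster_b = pairs$cluster_b[p],
        similarity = mean(sims), n_pairs = ncol(idx),
        n_empty = sum(empty)
      )
    })
  })
  class(out) <- c("similarity_series", class(out))
  out
}
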