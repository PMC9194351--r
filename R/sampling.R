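# equal-representation allocation with largest-remainder rounding:
# communities that cannot fill their equal share are saturated and the
# remainder is re-split among the rest
allocate_equal <- function(avail, n) {
  k <- length(avail)
  alloc <- setNames(integer(k), names(avail))
  remaining <- sort(names(avail))
  left <- n
  repeat {
    if (!length(remaining) || left <= 0L) break
    share <- left / length(remaining)
    sat <- remaining[avail[remaining] <= share]
    if (length(sat)) {
      alloc[sat] <- avail[sat]
      left <- left - sum(avail[sat])
      remaining <- setdiff(remaining, sat)
      next
    }
    # all remaining can absorb their share: largest-remainder split
    base <- floor(share)
    alloc[remaining] <- alloc[remaining] + as.integer(base)
    extra <- left - as.integer(base) * length(remaining)
    if (extra > 0L) {
      frac_order <- remaining # equal fractions: lexicographic tie-break
      alloc[frac_order[seq_len(extra)]] <-
        alloc[frac_order[seq_len(extra)]] + 1L
    }
    break
  }
  alloc
}

#' Stratified sample of tweets for content coding
#'
#' Draws up to `n_per_stratum` tweets from every (cluster, topic) stratum.
#' Strata with fewer tweets than requested are taken whole. Within a
#' stratum, communities are represented as equally as possible: each gets
#' an equal share (largest-remainder rounding, lexicographic tie-break),
#' communities that cannot fill their share contribute everything they
#' have, and the shortfall is re-split among the others. Sampling is
#' deterministic given `seed`.
#'
#' @param tweets A tweet tibble with `cluster`, `topic` and (when
#'   `balance_by_community`) `community` columns.
#' @param n_per_stratum Target sample size per stratum (default 100).
#' @param seed Integer seed.
#' @param balance_by_community Enforce equal community representation.
#' @param strata Optional tibble of `cluster`/`topic` combinations to
#'   sample; defaults to the combinations present in `tweets`. A declared
#'   stratum with no tweets yields an empty sample with a warning.
#' @return The sampled rows of `tweets`, with strata in sorted order.
#' @export
stratified_sample <- function(tweets, n_per_stratum = 100L, seed = 1L,
                              balance_by_community = TRUE, strata = NULL) {
  needed <- c("cluster", "topic", if (balance_by_community) "community")
  missing <- setdiff(needed, names(tweets))
  if (length(missing)) {
    abort(sprintf("tweets lack column(s): %s", paste(missing, collapse = ", ")))
  }
  strata <- (strata %||% distinct(tweets, .data$cluster, .data$topic)) |>
    arrange(.data$cluster, .data$topic)
  withr::with_seed(as.integer(seed), {
    out <- purrr::map_dfr(seq_len(nrow(strata)), function(i) {
      sub <- tweets |>
        filter(
          .data$cluster == strata$cluster[i],
          .data$topic == strata$topic[i]
        ) |>
        arrange(.data$tweet_id)
      if (nrow(sub) == 0L) {
        warn(sprintf(
          "empty stratum (%s, %s)", strata$cluster[i], strata$topic[i]
        ))
        return(sub)
      }
      if (nrow(sub) <= n_per_stratum) {
        return(sub)
      }
      if (!balance_by_community) {
        return(sub[sample.int(nrow(sub), n_per_stratum), , drop = FALSE])
      }
      avail <- table(sub$community)
      avail <- setNames(as.integer(avail), names(avail))
      alloc <- allocate_equal(avail, n_per_stratum)
      purrr::map_dfr(sort(names(alloc)), function(cm) {
        rows <- sub[sub$community == cm, , drop = FALSE]
        take <- alloc[[cm]]
        if (take >= nrow(rows)) rows else rows[sample.int(nrow(rows), take), ]
      })
    })
  })
  out
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction, with
#' `df = (rows - 1)(cols - 1)`. A zero row or column sum is an error.
#'
#' @param counts A numeric matrix or data frame of nonnegative counts.
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `n`.
#' @export
chi_square_test <- function(counts) {
  m <- as.matrix(counts)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("contingency table has a zero row or column sum")
  }
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(
    statistic = as.numeric(ht$statistic),
    df = as.integer(ht$parameter),
    p_value = as.numeric(ht$p.value),
    n = sum(m)
  )
}

#' Reconstruct coded counts from printed sample sizes and percentages
#'
#' Rebuilds a clusters-by-(misinformation, other) contingency table from
#' per-cluster sample sizes and misinformation percentages, rounding each
#' misinformation count to the nearest integer.
#'
#' @param n Named vector of per-cluster sample sizes.
#' @param percent Vector of misinformation percentages (0-100), aligned
#'   with `n`.
#' @return A `coded_counts` tibble with `cluster`, `n`, `misinformation`,
#'   `other`, plus a matrix in the `"table"` attribute ready for
#'   [chi_square_test()].
#' @export
coded_counts_from_percent <- function(n, percent) {
  stopifnot(length(n) == length(percent))
  mis <- round(n * percent / 100)
  tbl <- tibble(
    cluster = names(n) %||% as.character(seq_along(n)),
    n = as.integer(n),
    misinformation = as.integer(mis),
    other = as.integer(n - mis)
  )
  attr(tbl, "table") <- cbind(
    misinformation = tbl$misinformation,
    other = tbl$other
  )
  tbl
}
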