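#' Pipeline configuration
#'
#' Bundles the tunable parameters of the end-to-end sentinel pipeline with
#' the defaults used throughout the package: 15 sentinels per community, a
#' minimum community size, a domain retention threshold of 10 total
#' shares, a burst threshold of 2 with a 7-day burn-in, 5 latent semantic
#' components, centroid linkage, sample standard deviation, and UTC day
#' bucketing. Every parameter is echoed into the run manifest.
#'
#' @param k_sentinels Sentinels per community.
#' @param min_community_size Minimum community size for sentinel selection.
#' @param domain_min_total Domain retention threshold.
#' @param n_clusters Forced number of score clusters (`NULL` = silhouette
#'   optimal).
#' @param burst_threshold,burn_in_days Burst flagging parameters.
#' @param lsa_components Components for topical-tweet extraction.
#' @param match_threshold Cross-cluster near-duplicate threshold.
#' @param linkage `"centroid"` or `"average"`.
#' @param sd_type `"sample"` or `"population"`.
#' @param resolution,louvain_restarts Community detection parameters.
#' @param anchor_domain Sign anchor for the linked domain score.
#' @param covid_topic Name of the gate topic in `registry`.
#' @param registry Topic registry (default [default_topics()]).
#' @param seed Master seed.
#' @param tz Day-bucketing timezone.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k_sentinels = 15L,
                            min_community_size = 1L,
                            domain_min_total = 10L,
                            n_clusters = NULL,
                            burst_threshold = 2,
                            burn_in_days = 7L,
                            lsa_components = 5L,
                            match_threshold = 0.5,
                            linkage = "centroid",
                            sd_type = "sample",
                            resolution = 1,
                            louvain_restarts = 5L,
                            anchor_domain = NULL,
                            covid_topic = "covid",
                            registry = default_topics(),
                            seed = 1L,
                            tz = "UTC") {
  structure(
    as.list(environment()),
    class = "pipeline_config"
  )
}

#' Run the sentinel surveillance pipeline end to end
#'
#' Wires the stages together: retweet network from the corpus, largest
#' weakly connected component, Louvain communities on the symmetrized
#' directed modularity matrix, sentinel selection, linked-domain frequency
#' matrix and first-component scores, score clustering, per-capita topic
#' rates, daily documents and inter-cluster similarity, stationarity
#' diagnostic, burst flagging, and burst attribution via latent semantic
#' analysis. Artifacts are returned as a named list and, when `output_dir`
#' is given, also written as CSV/JSON files together with a `manifest.json`
#' recording every parameter and seed, so a rerun with the same manifest is
#' identical.
#'
#' @param tweets A tweet tibble ([read_tweet_stream()] or
#'   [generate_corpus()]`$tweets`).
#' @param window An [observation_window()].
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for artifact files.
#' @return A `pipeline_result` list: `network`, `lcc`, `partition`,
#'   `sentinels`, `coverage`, `domain_matrix`, `domain_score`, `clusters`,
#'   `rates`, `documents`, `similarity`, `stationarity`, `flags`,
#'   `attribution`, `manifest`.
#' @export
run_pipeline <- function(tweets, window, config = pipeline_config(),
                         output_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  net <- stage("network", retweet_network(tweets))
  lcc <- stage("lcc", largest_component(net))
  partition <- stage("communities", louvain_communities(
    lcc,
    seed = config$seed, resolution = config$resolution,
    n_restarts = config$louvain_restarts
  ))
  sentinels <- stage("sentinels", select_sentinels(
    lcc, partition,
    k = config$k_sentinels, min_size = config$min_community_size
  ))
  coverage <- stage("coverage", sentinel_coverage(
    lcc, partition,
    k = config$k_sentinels
  ))
  membership <- partition$assignment |>
    rename(community = "community")
  dfm <- stage("domains", build_domain_matrix(
    tweets, membership,
    min_total = config$domain_min_total
  ))
  score <- stage("domain_score", pca_first_component(
    dfm,
    anchor = config$anchor_domain
  ))
  clusters <- stage("clusters", cluster_scores(
    score,
    k = config$n_clusters, linkage = config$linkage
  ))
  cluster_map <- clusters$clusters |>
    mutate(community = as.integer(.data$community)) |>
    select("community", "cluster")

  covid <- stage("topic_filter", match_topic(
    tweets, config$covid_topic, config$registry
  ))
  counts <- covid |>
    inner_join(membership, by = "account_id") |>
    count(.data$community, name = "n_tweets") |>
    mutate(community = as.character(.data$community))
  aad <- stage("activity", {
    by_acc <- active_account_days(tweets, window)
    by_acc |>
      inner_join(membership, by = "account_id") |>
      group_by(.data$community) |>
      summarise(active_days = sum(.data$active_days), .groups = "drop") |>
      mutate(community = as.character(.data$community))
  })
  rates <- stage("rates", per_capita_rates(counts, aad))

  docs <- stage("documents", daily_documents(
    covid, membership, window
  ))
  sim <- stage("similarity", cluster_similarity(docs, cluster_map))
  stationarity <- stage("stationarity", {
    sim |>
      group_by(.data$cluster_a, .data$cluster_b) |>
      summarise(
        check = list(
          if (sum(!is.na(.data$similarity)) >= 10 &&
            sd(.data$similarity, na.rm = TRUE) > 0) {
            adf_check(.data$similarity, seed = config$seed)
          } else {
            tibble(
              statistic = NA_real_, p_value = NA_real_,
              verdict = "degenerate", n = sum(!is.na(.data$similarity))
            )
          }
        ),
        .groups = "drop"
      ) |>
      tidyr::unnest("check")
  })
  flags <- stage("flags", flag_bursts(
    sim,
    threshold = config$burst_threshold,
    burn_in = config$burn_in_days, sd_type = config$sd_type
  ))
  attribution <- stage("attribution", {
    if (nrow(flags) == 0L) {
      NULL
    } else {
      purrr::map_dfr(seq_len(nrow(flags)), function(i) {
        attribute_burst(
          flags[i, ], covid, membership, cluster_map, sim, window,
          threshold = config$burst_threshold,
          burn_in = config$burn_in_days, sd_type = config$sd_type,
          match_threshold = config$match_threshold,
          n_components = config$lsa_components
        )
      })
    }
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("sentinelnet")),
    window = list(
      start = format(window$start_day), end = format(window$end_day),
      tz = window$tz
    ),
    parameters = config[setdiff(names(config), "registry")],
    topics = names(config$registry)
  )
  result <- structure(
    list(
      network = net, lcc = lcc, partition = partition,
      sentinels = sentinels, coverage = coverage,
      domain_matrix = dfm, domain_score = score, clusters = clusters,
      rates = rates, documents = docs, similarity = sim,
      stationarity = stationarity, flags = flags,
      attribution = attribution, manifest = manifest
    ),
    class = "pipeline_result"
  )
  if (!is.null(output_dir)) write_pipeline_artifacts(result, output_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<pipeline_result> %d nodes (LCC %d), %d communities, ",
      "%d score clusters, %d burst flag(s)\n"
    ),
    nrow(x$network$nodes), nrow(x$lcc$nodes),
    max(x$partition$assignment$community), x$clusters$k, nrow(x$flags)
  ))
  invisible(x)
}

write_pipeline_artifacts <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(output_dir, name), row.names = FALSE)
  }
  wcsv(result$lcc$edges, "edges.csv")
  wcsv(result$partition$assignment, "partition.csv")
  wcsv(result$sentinels, "sentinels.csv")
  wcsv(tidy(result$coverage), "coverage.csv")
  wcsv(tidy(result$domain_score), "domain_scores.csv")
  wcsv(result$clusters$clusters, "clusters.csv")
  wcsv(as.data.frame(result$rates), "rates.csv")
  wcsv(
    result$similarity[, c(
      "day", "cluster_a", "cluster_b", "similarity"
    )],
    "similarity.csv"
  )
  wcsv(result$stationarity, "stationarity.csv")
  flags_out <- result$flags[, c(
    "day", "cluster_a", "cluster_b", "similarity", "burst"
  )]
  wcsv(flags_out, "flags.csv")
  if (!is.null(result$attribution)) {
    jsonlite::write_json(
      lapply(seq_len(nrow(result$attribution)), function(i) {
        r <- result$attribution[i, ]
        list(
          day = format(r$day), cluster_a = r$cluster_a,
          cluster_b = r$cluster_b, burst = r$burst,
          new_burst = r$new_burst, attributed = r$attributed,
          topical_a = r$topical_a[[1]], topical_b = r$topical_b[[1]],
          removed_a = r$removed_a[[1]], removed_b = r$removed_b[[1]]
        )
      }),
      file.path(output_dir, "attribution.json"),
      auto_unbox = TRUE
    )
  }
  jsonlite::write_json(
    result$manifest, file.path(output_dir, "manifest.json"),
    auto_unbox = TRUE, null = "null"
  )
  invisible(output_dir)
}
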