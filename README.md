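# sentinelnet

Sentinel-node surveillance of topical content — in particular health
misinformation — across online communities.

Monitoring everything posted about a topic on a large platform is
expensive and noisy. `sentinelnet` implements a data-light alternative
borrowed from epidemiological sentinel surveillance: detect communities in
a retweet network, select a handful of highly retweeted *sentinel*
accounts from each community, characterize communities by the news domains
they link, and then watch the daily text similarity between clusters of
communities for anomalous "bursts" that indicate content jumping between
otherwise separate audiences.

The pipeline stages, each usable on its own:

- **Retweet network and communities.** A weighted directed graph with
  `A_ij` = number of times account `j` retweeted account `i` (self-retweets
  excluded). Communities maximize the directed weighted modularity

  `Q = (1/w) Σ_ij (A_ij − w_i^in w_j^out / w) δ(C_i, C_j)`

  via a Louvain method run on the symmetrized modularity matrix
  `(B + Bᵀ)/2` (`louvain_communities()`). Partition stability across
  collection periods is measured by the Rand index and the z-Rand score,
  whose null moments are computed exactly under the permutation model
  (`rand_scores()`).
- **Sentinels.** The `k` most retweeted accounts per community
  (`select_sentinels()`, default `k = 15`), with in-degree coverage
  diagnostics (`sentinel_coverage()`) and attrition-aware activity
  accounting (`active_account_days()`).
- **Linked domain score.** A community × domain link-fraction matrix
  (links to twitter.com, URL shorteners, and rare domains excluded;
  `build_domain_matrix()`), its first principal component as a scalar
  media-preference score (`pca_first_component()`), hierarchical
  clustering of the scores with silhouette-based cut selection
  (`cluster_scores()`), and an optional join against an MBFC-style
  media-bias table (`join_bias_categories()`).
- **Keyword topics.** Substring-based topic filters with nested
  parent gates (`match_topic()`, shipped lists via `default_topics()`),
  per-capita and scaled per-capita tweet rates (`per_capita_rates()`),
  and a stratified sampling scaffold plus chi-square and Krippendorff's
  alpha for human-coded content (`stratified_sample()`,
  `chi_square_test()`, `krippendorff_alpha()`).
- **Burst detection and attribution.** Daily per-community documents of
  cleaned tweet trigrams (`daily_documents()`), mean inter-cluster cosine
  similarity (`cluster_similarity()`), the expanding-window burst score

  `H(A,B,t) = (s_t − mean_{τ<t} s_τ) / SD_{τ<t} s_τ`

  flagged at `H ≥ 2` after a 7-day burn-in (`flag_bursts()`), an augmented
  Dickey–Fuller stationarity diagnostic (`adf_check()`), and attribution
  of flagged days to driving tweets via latent semantic analysis with
  remove-and-recompute verification (`lsa_topical_tweets()`,
  `attribute_burst()`).
- **Synthetic corpora.** `generate_corpus()` plants community structure,
  domain poles, topic rates, and cross-cluster virality events with known
  ground truth, so the entire pipeline is testable offline.

Everything takes and returns tibbles, composes with the pipe, and offers
`tidy()`/`glance()` methods and ggplot2 `autoplot()`/`plot_*()` helpers.

## Worked example

A synthetic corpus with four communities in two media-preference poles and
one cross-cluster virality event planted on day 30:

```r
library(sentinelnet)

cfg  <- synthetic_config(events = virality_event(day = 30, communities = 1:4),
                         seed = 7)
corp <- generate_corpus(cfg)
res  <- run_pipeline(corp$tweets, corp$window,
                     pipeline_config(k_sentinels = 5, seed = 7))
res
#> <pipeline_result> 100 nodes (LCC 100), 4 communities, 2 score clusters, 1 burst flag(s)

glance(res$partition)
#> # A tibble: 1 × 5
#>   modularity n_communities n_nodes  seed resolution
#>        <dbl>         <int>   <int> <int>      <dbl>
#> 1      0.700             4     100     7          1

tidy(res$clusters)
#> # A tibble: 4 × 3
#>   community  score cluster
#>   <chr>      <dbl>   <int>
#> 1 1         -0.289       1
#> 2 2         -0.289       1
#> 3 3          0.289       2
#> 4 4          0.289       2

dplyr::select(res$flags, day, cluster_a, cluster_b, similarity, burst)
#> # A tibble: 1 × 5
#>   day        cluster_a cluster_b similarity burst
#>   <date>         <int>     <int>      <dbl> <dbl>
#> 1 2020-07-30         1         2      0.810  4.67

dplyr::select(res$attribution, day, burst, new_burst, attributed)
#> # A tibble: 1 × 4
#>   day        burst new_burst attributed
#>   <date>     <dbl>     <dbl> <lgl>
#> 1 2020-07-30  4.67      1.25 TRUE
```

Reading the output: Louvain recovers the four planted communities at
modularity 0.70; the linked-domain score splits them into the two planted
poles (scores ±0.289, two clusters); the only day whose inter-cluster
similarity bursts past two historical standard deviations is the planted
event day (H = 4.67); and removing the LSA-identified topical tweets that
appear near-verbatim in both clusters drops the recomputed score below
the flagging threshold (H = 1.25), attributing the burst to that content.

`plot_similarity_series(res$similarity, res$flags)`,
`plot_domain_scores(res$domain_score, res$clusters)` and
`plot_rate_heatmap()` draw the standard figures.

## Vignette

`vignettes/sentinel-surveillance.Rmd` documents the models, the
parameters and their defaults, the numerical conventions, the synthetic
generator's design, and known limitations.
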