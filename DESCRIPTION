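Package: sentinelnet
Title: Sentinel-Node Surveillance of Topical Content Across Online Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A data-light pipeline for monitoring how topical content, in
    particular health misinformation, circulates within and between online
    communities. Builds weighted directed retweet networks, detects
    communities by greedy maximization of directed modularity on a
    symmetrized modularity matrix, selects highly retweeted 'sentinel'
    accounts per community, scores communities by their linked-domain
    preferences via principal components analysis, tracks keyword-defined
    topics and per-capita posting rates, and flags days on which
    inter-cluster trigram cosine similarity is anomalously high relative
    to its history, attributing bursts to driving tweets with latent
    semantic analysis. Includes a synthetic corpus generator with planted
    community structure, domain preferences, and cross-cluster virality
    events for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lubridate,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
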