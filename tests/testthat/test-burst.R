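test_that("text cleaning applies the stated rules deterministically", {
  expect_equal(
    clean_text("Check https://x.co @bob THE masks")[[1]],
    c("check", "masks")
  )
  expect_equal(clean_text("the a of and")[[1]], character())
  # rule-by-rule reference scan on fixture sentences
  fixtures <- c(
    "RT @user Covid-19 cases RISING fast www.site.com/x",
    "masks work! t.co/abc123 say @cdc",
    "100 people can't be wrong"
  )
  ref <- lapply(fixtures, function(s) {
    s <- tolower(s)
    s <- gsub("(https?://\\S+)|(\\bt\\.co/\\S+)|(\\bwww\\.\\S+)", " ", s)
    s <- gsub("@\\w+", " ", s)
    toks <- regmatches(s, gregexpr("[a-z0-9]+(?:'[a-z0-9]+)*", s))[[1]]
    toks[!toks %in% default_stopwords()]
  })
  expect_equal(clean_text(fixtures), ref)
})

test_that("trigram vectors count within-tweet triples linearly", {
  v <- trigram_vector(list(c("a", "b", "c", "d")))
  expect_equal(sort(names(v)), c("a b c", "b c d"))
  expect_equal(unname(v[c("a b c", "b c d")]), c(1, 1))

  expect_equal(length(trigram_vector(list(c("a", "b")))), 0L)
  # no trigrams span tweet boundaries
  v2 <- trigram_vector(list(c("a", "b"), c("c", "d")))
  expect_equal(length(v2), 0L)

  tripled <- trigram_vector(rep(list(c("x", "y", "z", "w")), 3))
  expect_equal(unname(tripled["x y z"]), 3)
})

test_that("cosine similarity on counts is bounded, symmetric, exact", {
  a <- c("x" = 2, "y" = 1)
  b <- c("x" = 1, "y" = 2)
  expect_equal(cosine_similarity(a, b), 0.8)
  expect_equal(cosine_similarity(a, a), 1.0)
  expect_equal(cosine_similarity(a, c("z" = 5)), 0)
  expect_equal(cosine_similarity(a, setNames(numeric(), character())), 0)
  withr::with_seed(9, {
    for (rep in 1:10) {
      v1 <- setNames(rpois(6, 2), sample(letters, 6))
      v2 <- setNames(rpois(6, 2), sample(letters, 6))
      s <- cosine_similarity(v1, v2)
      expect_gte(s, 0)
      expect_lte(s, 1)
      expect_equal(s, cosine_similarity(v2, v1))
    }
  })
  expect_equal(trigram_jaccard(a, b), 1)
  expect_equal(trigram_jaccard(a, c("x" = 1, "q" = 1)), 1 / 3)
})

test_that("daily cluster similarity averages all community pairs", {
  win <- observation_window("2020-07-01", "2020-07-01")
  memb <- tibble::tibble(
    account_id = c("a1", "a2", "b1", "b2"),
    community = 1:4
  )
  clus <- tibble::tibble(community = 1:4, cluster = c(1, 1, 2, 2))
  texts <- c(
    "alpha beta gamma delta",
    "alpha beta gamma epsilon",
    "alpha beta gamma zeta",
    "omega psi chi phi"
  )
  tw <- make_tweets(memb$account_id, text = texts)
  docs <- daily_documents(tw, memb, win)
  sim <- cluster_similarity(docs, clus)
  vecs <- lapply(
    clean_text(texts),
    function(tt) trigram_vector(list(tt))
  )
  hand <- mean(c(
    cosine_similarity(vecs[[1]], vecs[[3]]),
    cosine_similarity(vecs[[1]], vecs[[4]]),
    cosine_similarity(vecs[[2]], vecs[[3]]),
    cosine_similarity(vecs[[2]], vecs[[4]])
  ))
  expect_equal(sim$similarity, hand)
  expect_equal(sim$n_pairs, 4L)

  # identical documents give similarity 1; singleton clusters reduce to
  # the single pair cosine
  same <- make_tweets(memb$account_id, text = "one two three four")
  sim1 <- cluster_similarity(daily_documents(same, memb, win), clus)
  expect_equal(sim1$similarity, 1.0)
  single <- tibble::tibble(community = 1:2, cluster = 1:2)
  memb2 <- memb[1:2, ]
  sim2 <- cluster_similarity(
    daily_documents(tw[1:2, ], memb2, win), single
  )
  expect_equal(
    sim2$similarity, cosine_similarity(vecs[[1]], vecs[[2]])
  )

  # invariant to community order within clusters; empty docs contribute 0
  clus_perm <- clus[c(3, 1, 4, 2), ]
  expect_equal(
    cluster_similarity(docs, clus_perm)$similarity, sim$similarity
  )
  empty_day <- make_tweets(memb$account_id[1:3], text = texts[1:3])
  sim0 <- cluster_similarity(
    daily_documents(empty_day, memb, win), clus
  )
  expect_equal(sim0$n_empty, 2L)

  # within-cluster diagnostic series
  simw <- cluster_similarity(docs, clus, include_within = TRUE)
  w11 <- simw[simw$cluster_a == 1 & simw$cluster_b == 1, ]
  expect_equal(
    w11$similarity, cosine_similarity(vecs[[1]], vecs[[2]])
  )
})

toy_series <- function(values, start = "2020-07-01") {
  tibble::tibble(
    day = seq(as.Date(start), by = "day", length.out = length(values)),
    cluster_a = 1, cluster_b = 2, similarity = values
  )
}

test_that("burst score equals the expanding-window z-score", {
  s <- toy_series(c(0.1, 0.3, 0.4))
  scored <- burst_scores(s, burn_in = 2)
  expect_equal(
    scored$burst[3], (0.4 - 0.2) / sd(c(0.1, 0.3))
  )
  expect_equal(scored$burst[3], sqrt(2), tolerance = 1e-12)
  expect_true(all(is.na(scored$burst[1:2])))

  # day at the historical mean scores zero
  s2 <- toy_series(c(0.1, 0.3, 0.2))
  expect_equal(burst_scores(s2, burn_in = 2)$burst[3], 0)

  # constant history: undefined, never infinite
  s3 <- toy_series(c(0.2, 0.2, 0.5))
  expect_true(is.na(burst_scores(s3, burn_in = 2)$burst[3]))

  # population SD convention
  pop <- burst_scores(s, burn_in = 2, sd_type = "population")
  expect_equal(pop$burst[3], (0.4 - 0.2) / 0.1)

  # invariant to affine rescaling with positive slope
  withr::with_seed(14, {
    vals <- runif(20)
    a <- burst_scores(toy_series(vals), burn_in = 7)$burst
    b <- burst_scores(toy_series(3 * vals + 2), burn_in = 7)$burst
    expect_equal(a, b)
  })
})

test_that("flagging respects threshold and burn-in", {
  withr::with_seed(15, {
    vals <- 0.2 + 0.01 * sin(1:40) + rnorm(40, 0, 0.002)
  })
  vals[30] <- vals[30] + 5 * sd(vals[1:29])
  flags <- flag_bursts(toy_series(vals), threshold = 2, burn_in = 7)
  expect_equal(flags$day, as.Date("2020-07-01") + 29)

  expect_equal(nrow(flag_bursts(toy_series(rep(0.3, 30)))), 0L)

  spiky <- rep(0.1, 30)
  spiky[3] <- 0.9
  early <- flag_bursts(toy_series(spiky), burn_in = 7)
  expect_false(as.Date("2020-07-03") %in% early$day)
})

test_that("dickey-fuller check distinguishes noise from walks", {
  n_ok <- 0
  for (seed in 1:20) {
    x <- withr::with_seed(100 + seed, rnorm(200, mean = 0.3, sd = 0.05))
    v <- adf_check(x, n_sim = 1000, seed = 1)
    n_ok <- n_ok + (v$verdict == "stationary")
  }
  expect_gte(n_ok, 19)

  n_walk <- 0
  for (seed in 1:20) {
    x <- withr::with_seed(200 + seed, cumsum(rnorm(200)))
    v <- adf_check(x, n_sim = 1000, seed = 1)
    n_walk <- n_walk + (v$verdict == "non-stationary")
  }
  expect_gte(n_walk, 15)

  expect_equal(adf_check(rep(0.5, 30))$verdict, "degenerate")
  expect_error(adf_check(rnorm(5)), "at least 10")
})

test_that("lsa isolates dominant and orthogonal structures", {
  ident <- make_tweets(
    "a",
    text = c(
      rep("viral claim spreading fast tonight", 3),
      paste("unique", letters[1:7], "tokens", LETTERS[1:7], "here", 1:7)
    )
  )
  picks <- lsa_topical_tweets(ident, n_components = 1)
  expect_true(all(ident$tweet_id[1:3] %in% picks$tweet_id))
  expect_true(all(picks$tweet_id %in% ident$tweet_id[1:3]))

  # mutually orthogonal tweets with distinct weights: each component
  # isolates the corresponding tweet
  orth_texts <- vapply(1:5, function(k) {
    paste(rep(
      paste("block", k, "word", k, "unit", k), 6 - k
    ), collapse = " ")
  }, character(1))
  orth <- make_tweets("a", text = orth_texts)
  p5 <- lsa_topical_tweets(orth, n_components = 5)
  expect_setequal(p5$tweet_id, orth$tweet_id)
  expect_equal(nrow(p5), 5L)

  # empty-after-cleaning tweets are dropped before the svd; rank shortfall
  # warns and degrades
  mix <- make_tweets("a", text = c(
    "the and of", rep("identical viral claim repeated nightly", 2)
  ))
  expect_warning(pm <- lsa_topical_tweets(mix, n_components = 5), "rank")
  expect_true(all(pm$tweet_id %in% mix$tweet_id[2:3]))
  expect_error(
    lsa_topical_tweets(make_tweets("a", text = "the and")),
    "nonempty"
  )
})

test_that("planted cross-cluster events are attributed, unrelated bursts are not", {
  win <- observation_window("2020-07-01", "2020-07-20")
  memb <- tibble::tibble(account_id = c("a1", "b1"), community = 1:2)
  clus <- tibble::tibble(community = 1:2, cluster = 1:2)
  viral <- "breaking shared claim spreading everywhere tonight folks"
  base_a <- "alpha beta gamma delta epsilon iota"
  base_b <- "omega psi chi phi upsilon tau"
  shared_bg <- "common daily chatter words here"
  days <- seq(win$start_day, win$end_day, by = "day")
  mk_day <- function(d, texts, accounts) {
    make_tweets(accounts,
      text = texts, day = d,
      tweet_id = sprintf("%s-%s-%02d", accounts, format(d), seq_along(texts))
    )
  }
  rows <- list()
  for (i in seq_along(days)) {
    # the volume of mutually shared content varies by day so the
    # similarity history has nonzero, bounded variance
    shared_today <- if (i %% 3 == 0) {
      c(shared_bg, "extra mutual topic phrase today")
    } else {
      shared_bg
    }
    rows[[length(rows) + 1]] <- mk_day(
      days[i], c(base_a, shared_today), "a1"
    )
    rows[[length(rows) + 1]] <- mk_day(
      days[i], c(base_b, shared_today), "b1"
    )
  }
  tw <- dplyr::bind_rows(rows)
  event_day <- days[15]
  ev <- dplyr::bind_rows(
    mk_day(event_day, rep(viral, 4), "a1"),
    mk_day(event_day, rep(viral, 4), "b1")
  ) |> dplyr::mutate(tweet_id = paste0("ev", dplyr::row_number()))
  tw_ev <- dplyr::bind_rows(tw, ev)

  docs <- daily_documents(tw_ev, memb, win)
  sim <- cluster_similarity(docs, clus)
  flags <- flag_bursts(sim, threshold = 2, burn_in = 7)
  expect_true(event_day %in% flags$day)
  flag <- flags[flags$day == event_day, ]
  att <- suppressWarnings(attribute_burst(
    flag, tw_ev, memb, clus, sim, win,
    threshold = 2, burn_in = 7
  ))
  expect_true(att$attributed)
  expect_lt(att$new_burst, 2)
  expect_true(all(ev$tweet_id[1:4] %in% att$removed_a[[1]]))

  # a burst whose clusters converge in vocabulary without sharing
  # near-duplicate tweets stays unattributed at a strict match threshold
  loud_a <- "common daily chatter words combined alpha"
  loud_b <- "common daily chatter words combined omega"
  un <- dplyr::bind_rows(
    tw |> dplyr::filter(tweet_day(timestamp, win) != event_day),
    mk_day(event_day, c(base_a, rep(loud_a, 12)), "a1") |>
      dplyr::mutate(tweet_id = paste0("la", 1:13)),
    mk_day(event_day, c(base_b, rep(loud_b, 12)), "b1") |>
      dplyr::mutate(tweet_id = paste0("lb", 1:13))
  )
  docs_un <- daily_documents(un, memb, win)
  sim_un <- cluster_similarity(docs_un, clus)
  flags_un <- flag_bursts(sim_un, threshold = 2, burn_in = 7)
  expect_true(event_day %in% flags_un$day)
  att_un <- suppressWarnings(attribute_burst(
    flags_un[flags_un$day == event_day, ], un, memb, clus, sim_un, win,
    match_threshold = 0.9
  ))
  expect_false(att_un$attributed)
  expect_equal(length(att_un$removed_a[[1]]), 0L)

  # removing zero tweets leaves the similarity unchanged
  att_none <- suppressWarnings(attribute_burst(
    flag, tw_ev, memb, clus, sim, win,
    match_threshold = 1.01
  ))
  expect_equal(att_none$new_similarity, flag$similarity)
  expect_false(att_none$attributed)

  # a cluster with all tweets removed on the day yields similarity 0
  gone <- tw_ev |> dplyr::filter(
    !(account_id == "a1" &
      tweet_day(timestamp, win) == event_day)
  )
  docs_gone <- daily_documents(gone, memb, win)
  sim_gone <- cluster_similarity(docs_gone, clus)
  expect_equal(
    sim_gone$similarity[sim_gone$day == event_day], 0
  )
  expect_equal(
    sim_gone$n_empty[sim_gone$day == event_day], 1L
  )
})
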