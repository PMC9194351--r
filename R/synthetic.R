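#' Configuration for the synthetic tweet corpus generator
#'
#' Describes a corpus with planted structure at every level the pipeline
#' analyzes: assortative retweeting within communities (a retweet stays in
#' its community with probability `p_in`, and targets are chosen by
#' preferential attachment on in-degree, giving the heavy-tailed in-degree
#' profile sentinel coverage relies on); disjoint per-pole domain-sharing
#' preferences (the first half of the communities links to the left pole's
#' domains, the second half to the right pole's); community-specific
#' background vocabularies with Zipf-like token frequencies, so baseline
#' trigram overlap between communities is driven only by a shared daily
#' "news" channel; a weekly news cycle (each day carries
#' `n_news_phrases` fresh phrases, attached to a deterministic quota
#' `news_base * (1 + news_amplitude * sin(2 pi day / 7))` of each
#' community's COVID tweets), which gives the similarity series a bounded,
#' cyclic baseline; per-community keyword-topic emission rates; and
#' optional planted cross-community virality events injected verbatim on
#' known days.
#'
#' @param n_communities,accounts_per_community,days Corpus dimensions.
#' @param start_day First calendar day.
#' @param tz Timezone for the window.
#' @param p_in Probability a retweet stays within the retweeter's
#'   community.
#' @param tweets_per_account_day Poisson mean of daily tweets per account.
#' @param retweet_fraction Fraction of tweets that are retweets.
#' @param covid_rate Probability a tweet carries the COVID gate keyword.
#' @param news_base,news_amplitude,n_news_phrases,news_phrase_len Weekly
#'   news-cycle channel shared across communities.
#' @param vocab_size,zipf_exponent Community background vocabularies.
#' @param url_rate Probability a tweet links one of its community's pole
#'   domains.
#' @param topics List of planted keyword topics, each a list with `name`,
#'   `insert` (text appended to the tweet) and `rates` (per-community
#'   emission probability within COVID tweets).
#' @param events A tibble of planted events (see [virality_event()]), or
#'   `NULL`.
#' @param seed Integer seed; the same seed yields a byte-identical corpus.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_communities = 4L,
                             accounts_per_community = 25L,
                             days = 42L,
                             start_day = as.Date("2020-07-01"),
                             tz = "UTC",
                             p_in = 0.95,
                             tweets_per_account_day = 3,
                             retweet_fraction = 0.5,
                             covid_rate = 0.7,
                             news_base = 0.3,
                             news_amplitude = 0.6,
                             n_news_phrases = 6L,
                             news_phrase_len = 5L,
                             vocab_size = 150L,
                             zipf_exponent = 1.05,
                             url_rate = 0.3,
                             topics = default_planted_topics(n_communities),
                             events = NULL,
                             seed = 1L) {
  if (n_communities < 1L || accounts_per_community < 1L) {
    abort("need at least one community and one account")
  }
  stopifnot(
    p_in >= 0, p_in <= 1, covid_rate >= 0, covid_rate <= 1,
    retweet_fraction >= 0, retweet_fraction <= 1, days >= 1
  )
  if (!is.null(events)) {
    if (any(events$day < 1L | events$day > days)) {
      abort("planted event days must lie inside the window")
    }
  }
  structure(
    list(
      n_communities = as.integer(n_communities),
      accounts_per_community = as.integer(accounts_per_community),
      days = as.integer(days),
      start_day = as.Date(start_day),
      tz = tz,
      p_in = p_in,
      tweets_per_account_day = tweets_per_account_day,
      retweet_fraction = retweet_fraction,
      covid_rate = covid_rate,
      news_base = news_base,
      news_amplitude = news_amplitude,
      n_news_phrases = as.integer(n_news_phrases),
      news_phrase_len = as.integer(news_phrase_len),
      vocab_size = as.integer(vocab_size),
      zipf_exponent = zipf_exponent,
      url_rate = url_rate,
      topics = topics,
      events = events,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' @rdname synthetic_config
#' @export
default_planted_topics <- function(n_communities = 4L) {
  half <- ceiling(n_communities / 2)
  right <- c(rep(FALSE, half), rep(TRUE, n_communities - half))
  list(
    list(
      name = "facemasks", insert = "mask",
      rates = ifelse(right, 0.12, 0.03)
    ),
    list(
      name = "hydroxychloroquine", insert = "hcq",
      rates = ifelse(right, 0.08, 0.01)
    ),
    list(
      name = "downplaying_severity",
      insert = "death rate lower than flu mild",
      rates = ifelse(right, 0.05, 0.005)
    )
  )
}

#' Planted cross-community virality event
#'
#' @param day Day offset within the window (1 = first day).
#' @param communities Integer vector of community indices receiving the
#'   event.
#' @param copies Identical copies injected per community.
#' @param text Event text; the default is a fixed viral-claim template that
#'   passes the COVID gate.
#' @return A one-row event tibble for [synthetic_config()].
#' @export
virality_event <- function(day, communities, copies = 12L, text = NULL) {
  text <- text %||% paste(
    "breaking covid report agency quietly updated death statistics",
    "showing only small fraction certified deaths caused directly"
  )
  tibble(
    day = as.integer(day),
    communities = list(as.integer(communities)),
    copies = as.integer(copies),
    text = text
  )
}

#' Pole domains used by the synthetic generator
#'
#' @param pole `"left"` or `"right"`.
#' @return Character vector of synthetic domain names.
#' @export
synthetic_pole_domains <- function(pole = c("left", "right")) {
  pole <- match.arg(pole)
  if (pole == "left") {
    paste0("leftnews", 1:6, ".org")
  } else {
    paste0("rightnews", 1:6, ".org")
  }
}

#' Generate a synthetic tweet corpus with planted ground truth
#'
#' Realizes a [synthetic_config()] into a tweet tibble plus the planted
#' truth. Deterministic given the config's seed.
#'
#' @param config A [synthetic_config()].
#' @return A list with `tweets` (a tweet tibble), `window` (the matching
#'   [observation_window()]) and `truth`: `membership`
#'   (`account_id`/`community`), `poles` (`community`/`pole`), and
#'   `events` (event day, communities and injected `tweet_ids`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  nc <- cfg$n_communities
  na <- cfg$accounts_per_community
  accounts <- tibble(
    community = rep(seq_len(nc), each = na),
    account_id = sprintf("c%02da%03d", rep(seq_len(nc), each = na), seq_len(na))
  )
  half <- ceiling(nc / 2)
  poles <- tibble(
    community = seq_len(nc),
    pole = ifelse(seq_len(nc) <= half, "left", "right")
  )
  vocab <- lapply(seq_len(nc), function(cc) {
    sprintf("w%02dx%03d", cc, seq_len(cfg$vocab_size))
  })
  zipf_w <- (seq_len(cfg$vocab_size))^(-cfg$zipf_exponent)
  news_vocab <- sprintf("news%04d", 1:400)
  day_phrases <- lapply(seq_len(cfg$days), function(d) {
    vapply(seq_len(cfg$n_news_phrases), function(i) {
      paste(sample(news_vocab, cfg$news_phrase_len), collapse = " ")
    }, character(1))
  })
  pole_domains <- list(
    left = synthetic_pole_domains("left"),
    right = synthetic_pole_domains("right")
  )
  indeg <- setNames(rep(0, nrow(accounts)), accounts$account_id)

  rows <- vector("list", cfg$days)
  next_id <- 1L
  for (d in seq_len(cfg$days)) {
    p_news <- cfg$news_base *
      (1 + cfg$news_amplitude * sin(2 * pi * d / 7))
    p_news <- min(max(p_news, 0), 1)
    day_rows <- vector("list", nc)
    for (cc in seq_len(nc)) {
      members <- accounts$account_id[accounts$community == cc]
      n_tw <- rpois(length(members), cfg$tweets_per_account_day)
      senders <- rep(members, n_tw)
      total <- length(senders)
      if (total == 0L) next
      is_covid <- runif(total) < cfg$covid_rate
      texts <- vapply(seq_len(total), function(i) {
        len <- sample(6:12, 1)
        toks <- sample(vocab[[cc]], len, replace = TRUE, prob = zipf_w)
        paste(toks, collapse = " ")
      }, character(1))
      texts[is_covid] <- paste("covid", texts[is_covid])
      # planted keyword topics within covid tweets
      for (tp in cfg$topics) {
        hit <- is_covid & runif(total) < tp$rates[cc]
        texts[hit] <- paste(texts[hit], tp$insert)
      }
      # shared news channel: deterministic per-phrase quota of covid tweets
      covid_idx <- which(is_covid)
      if (length(covid_idx) && p_news > 0) {
        quota <- round(p_news * length(covid_idx) / cfg$n_news_phrases)
        for (ph in day_phrases[[d]]) {
          if (quota < 1L) break
          chosen <- sample(covid_idx, min(quota, length(covid_idx)))
          texts[chosen] <- paste(texts[chosen], ph)
        }
      }
      # retweet attribution with assortative targeting and preferential
      # attachment on in-degree
      is_rt <- runif(total) < cfg$retweet_fraction
      rt_of <- rep(NA_character_, total)
      for (i in which(is_rt)) {
        target_comm <- if (nc == 1L || runif(1) < cfg$p_in) {
          cc
        } else {
          sample(setdiff(seq_len(nc), cc), 1)
        }
        cand <- accounts$account_id[accounts$community == target_comm]
        cand <- setdiff(cand, senders[i])
        wts <- indeg[cand] + 1
        src <- sample(cand, 1, prob = wts)
        rt_of[i] <- src
        indeg[src] <- indeg[src] + 1
      }
      urls <- lapply(seq_len(total), function(i) {
        if (runif(1) < cfg$url_rate) {
          dom <- sample(pole_domains[[poles$pole[cc]]], 1)
          sprintf("https://www.%s/a%06d", dom, sample.int(1e6, 1))
        } else {
          character()
        }
      })
      ids <- sprintf("t%08d", next_id:(next_id + total - 1L))
      next_id <- next_id + total
      day_rows[[cc]] <- tibble(
        tweet_id = ids,
        account_id = senders,
        timestamp = lubridate::as_datetime(cfg$start_day + d - 1L) +
          sort(sample.int(86399L, total, replace = TRUE)),
        text = texts,
        retweeted_account_id = rt_of,
        urls = urls
      )
    }
    rows[[d]] <- bind_rows(day_rows)
  }
  tweets <- bind_rows(rows)

  # planted events: verbatim copies injected on their days
  event_truth <- NULL
  if (!is.null(cfg$events) && nrow(cfg$events)) {
    ev_rows <- vector("list", nrow(cfg$events))
    ev_ids <- vector("list", nrow(cfg$events))
    for (e in seq_len(nrow(cfg$events))) {
      comms <- cfg$events$communities[[e]]
      copies <- cfg$events$copies[e]
      n_new <- length(comms) * copies
      if (n_new == 0L) {
        ev_ids[[e]] <- character()
        next
      }
      senders <- unlist(lapply(comms, function(cc) {
        sample(accounts$account_id[accounts$community == cc], copies,
          replace = copies > cfg$accounts_per_community
        )
      }))
      ids <- sprintf("t%08d", next_id:(next_id + n_new - 1L))
      next_id <- next_id + n_new
      ev_rows[[e]] <- tibble(
        tweet_id = ids,
        account_id = senders,
        timestamp = lubridate::as_datetime(
          cfg$start_day + cfg$events$day[e] - 1L
        ) + sample.int(86399L, n_new, replace = TRUE),
        text = cfg$events$text[e],
        retweeted_account_id = NA_character_,
        urls = replicate(n_new, character(), simplify = FALSE)
      )
      ev_ids[[e]] <- ids
    }
    tweets <- bind_rows(tweets, bind_rows(ev_rows))
    event_truth <- cfg$events |> mutate(tweet_ids = ev_ids)
  }

  window <- observation_window(
    cfg$start_day, cfg$start_day + cfg$days - 1L,
    tz = cfg$tz
  )
  list(
    tweets = tweets,
    window = window,
    truth = list(
      membership = accounts[, c("account_id", "community")],
      poles = poles,
      events = event_truth
    )
  )
}
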