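#' Keyword topic specifications
#'
#' A topic is defined by a set of lowercase substrings; a tweet matches when
#' its lowercased text contains at least one of them. Topics may be nested:
#' a topic with a `parent` only matches within the parent's matches, so for
#' instance a hydroxychloroquine topic gated on a COVID topic matches only
#' COVID tweets mentioning hydroxychloroquine. `topic_registry()` collects
#' specs and validates the parent links.
#'
#' @param name Topic name.
#' @param substrings Nonempty character vector of search strings (matched
#'   case-insensitively as plain substrings).
#' @param parent Optional name of the enclosing topic.
#' @return `topic_spec()`: a `topic_spec` object. `topic_registry()`: a
#'   named list of specs.
#' @export
topic_spec <- function(name, substrings, parent = NULL) {
  substrings <- tolower(as.character(substrings))
  substrings <- substrings[nzchar(substrings)]
  if (!length(substrings)) abort("a topic needs at least one substring")
  structure(
    list(name = name, substrings = substrings, parent = parent),
    class = "topic_spec"
  )
}

#' @rdname topic_spec
#' @param ... `topic_spec` objects.
#' @export
topic_registry <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1]]) &&
    !inherits(specs[[1]], "topic_spec")) {
    specs <- specs[[1]]
  }
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  for (s in specs) {
    seen <- s$name
    p <- s$parent
    while (!is.null(p)) {
      if (!p %in% names(specs)) {
        abort(sprintf("topic '%s' names undefined parent '%s'", s$name, p))
      }
      if (p %in% seen) abort("cycle in topic parent chain")
      seen <- c(seen, p)
      p <- specs[[p]]$parent
    }
  }
  specs
}

#' Shipped topic keyword lists
#'
#' Loads the package's default topic registry: a COVID gate topic plus
#' nested topics for the misinformation families tracked in the package
#' (plandemic, hydroxychloroquine, facemasks, COVID mortality, COVID
#' severity with a downplaying-severity subset, and vaccines with vaccine
#' hesitancy and vaccine misinformation subsets). The lists live as
#' editable one-substring-per-line text files under
#' `inst/extdata/topics/` with a `topics.csv` manifest; the quoted
#' anchor phrases are documented there and the remainder of each list is a
#' reconstruction, clearly marked as such.
#'
#' @param dir Directory containing `topics.csv` and the list files;
#'   defaults to the installed copies.
#' @return A topic registry (named list of [topic_spec()]s).
#' @export
default_topics <- function(dir = system.file("extdata", "topics",
                             package = "sentinelnet")) {
  manifest <- utils::read.csv(file.path(dir, "topics.csv"),
    colClasses = "character"
  )
  specs <- lapply(seq_len(nrow(manifest)), function(i) {
    words <- readLines(file.path(dir, manifest$file[i]), encoding = "UTF-8")
    words <- trimws(words)
    words <- words[nzchar(words) & !startsWith(words, "#")]
    topic_spec(
      manifest$name[i], words,
      parent = if (nzchar(manifest$parent[i])) manifest$parent[i] else NULL
    )
  })
  topic_registry(specs)
}

topic_matches_text <- function(text, spec, word_boundary = FALSE) {
  lowered <- stringr::str_to_lower(text)
  hit <- rep(FALSE, length(text))
  for (s in spec$substrings) {
    pat <- if (word_boundary) {
      stringr::regex(paste0(
        "\\b", stringr::str_replace_all(s, "([.^$|()\\[\\]{}*+?\\\\])", "\\\\\\1"),
        "\\b"
      ))
    } else {
      stringr::fixed(s)
    }
    hit <- hit | stringr::str_detect(lowered, pat)
  }
  hit
}

#' Match tweets against a keyword topic
#'
#' Returns the tweets whose text contains at least one of the topic's
#' substrings and that also match the topic's parent chain. Matching is
#' plain lowercase substring containment by default, so `"mask"` matches
#' `"masks"` and also `"unmasked"`; set `word_boundary = TRUE` for
#' whole-word matching.
#'
#' @param tweets A tweet tibble.
#' @param topic A `topic_spec` or a topic name resolved in `registry`.
#' @param registry A [topic_registry()]; required when the topic (or its
#'   ancestors) are named.
#' @param word_boundary Match on word boundaries instead of raw substrings.
#' @return The matching subset of `tweets`.
#' @export
match_topic <- function(tweets, topic, registry = NULL,
                        word_boundary = FALSE) {
  spec <- if (inherits(topic, "topic_spec")) {
    topic
  } else {
    if (is.null(registry) || !topic %in% names(registry)) {
      abort(sprintf("unknown topic '%s'", topic))
    }
    registry[[topic]]
  }
  if (!is.null(spec$parent)) {
    if (is.null(registry) || !spec$parent %in% names(registry)) {
      abort(sprintf("undefined parent topic '%s'", spec$parent))
    }
    tweets <- match_topic(tweets, spec$parent, registry, word_boundary)
  }
  tweets[topic_matches_text(tweets$text, spec, word_boundary), , drop = FALSE]
}

#' Per-capita and scaled per-capita topical tweet rates
#'
#' For each community, the per-capita rate is the count of topical tweets
#' divided by the community's active account days, and the scaled rate
#' divides each community's per-capita rate by the sum of per-capita rates
#' across communities, so scaled rates sum to 1 and express each
#' community's share of engagement net of attrition.
#'
#' @param counts A tibble with `community` and `n_tweets` (or a named
#'   vector).
#' @param active_days A tibble with `community` and `active_days` (or a
#'   named vector); must be positive for every counted community.
#' @return A `rate_table` tibble: `community`, `n_tweets`, `active_days`,
#'   `rate`, `scaled_rate`. With all-zero counts the scaled rates are
#'   reported as zero with a warning.
#' @export
per_capita_rates <- function(counts, active_days) {
  if (!is.data.frame(counts)) {
    counts <- tibble(community = names(counts), n_tweets = as.numeric(counts))
  }
  if (!is.data.frame(active_days)) {
    active_days <- tibble(
      community = names(active_days),
      active_days = as.numeric(active_days)
    )
  }
  tbl <- left_join(counts, active_days, by = "community")
  if (any(is.na(tbl$active_days) | tbl$active_days <= 0)) {
    abort("every counted community needs positive active account days")
  }
  tbl$rate <- tbl$n_tweets / tbl$active_days
  total <- sum(tbl$rate)
  if (total > 0) {
    tbl$scaled_rate <- tbl$rate / total
  } else {
    warn("all rates are zero; scaled rates undefined, reported as 0")
    tbl$scaled_rate <- 0
  }
  class(tbl) <- c("rate_table", class(tbl))
  tbl
}

#' Daily topical tweets per 15 active accounts
#'
#' Expresses daily topical volume for a group of monitored accounts on a
#' per-15-accounts basis: the day's topical tweet count divided by the
#' number of accounts active that day, times 15. This is the display
#' normalization used for daily time-series plots of sentinel activity.
#'
#' @param topical_tweets Tweet tibble already filtered to the topic.
#' @param all_tweets Tweet tibble of all monitored tweets (defines
#'   activity).
#' @param window An [observation_window()].
#' @param accounts Accounts under monitoring; defaults to accounts in
#'   `all_tweets`.
#' @return A tibble with `day`, `n_tweets`, `n_active`, `per_15`.
#' @export
daily_rate_per15 <- function(topical_tweets, all_tweets, window,
                             accounts = NULL) {
  act <- active_accounts_by_day(all_tweets, window, accounts)
  day <- tweet_day(topical_tweets$timestamp, window)
  cnt <- tibble(day = day) |> count(.data$day, name = "n_tweets")
  act |>
    left_join(cnt, by = "day") |>
    mutate(
      n_tweets = ifelse(is.na(.data$n_tweets), 0L, .data$n_tweets),
      per_15 = ifelse(
        .data$n_active > 0, .data$n_tweets / .data$n_active * 15, NA_real_
      )
    )
}
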