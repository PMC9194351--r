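# fixture builders shared across tests

make_tweets <- function(account_id,
                        text = "",
                        retweeted_account_id = NA_character_,
                        day = as.Date("2020-07-01"),
                        urls = NULL,
                        tweet_id = NULL) {
  n <- max(
    length(account_id), length(text), length(retweeted_account_id),
    length(day)
  )
  account_id <- rep_len(account_id, n)
  text <- rep_len(text, n)
  retweeted_account_id <- rep_len(retweeted_account_id, n)
  day <- rep_len(as.Date(day), n)
  tibble::tibble(
    tweet_id = tweet_id %||% sprintf("tw%05d", seq_len(n)),
    account_id = account_id,
    timestamp = lubridate::as_datetime(day) + seq_len(n),
    text = text,
    retweeted_account_id = retweeted_account_id,
    urls = urls %||% replicate(n, character(), simplify = FALSE)
  )
}

# one tweet row per retweet occurrence: retweeter -> source with multiplicity
tweets_from_retweets <- function(source, retweeter, times = 1L) {
  src <- rep(source, times)
  rtw <- rep(retweeter, times)
  make_tweets(account_id = rtw, retweeted_account_id = src)
}

`%||%` <- rlang::`%||%`
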