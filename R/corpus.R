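#' Define an observation window
#'
#' An observation window fixes the calendar span of an analysis and the
#' timezone used to bucket timestamps into days. Every daily aggregation in
#' the package (activity accounting, daily documents, similarity series) uses
#' the window's timezone, so results are consistent across stages.
#'
#' @param start_day,end_day Calendar dates (`Date` or anything
#'   `as.Date()` understands) delimiting the window, inclusive.
#' @param tz Timezone identifier used for day bucketing. Defaults to `"UTC"`.
#'   Reproducing analyses anchored to US news cycles typically requires
#'   `"America/New_York"`.
#'
#' @return An `observation_window` object.
#' @examples
#' observation_window("2020-07-01", "2021-01-06", tz = "America/New_York")
#' @export
observation_window <- function(start_day, end_day, tz = "UTC") {
  start_day <- as.Date(start_day)
  end_day <- as.Date(end_day)
  if (is.na(start_day) || is.na(end_day)) {
    abort("start_day and end_day must be parseable dates")
  }
  if (start_day > end_day) {
    abort("start_day must not be after end_day")
  }
  structure(
    list(start_day = start_day, end_day = end_day, tz = tz),
    class = "observation_window"
  )
}

#' @export
print.observation_window <- function(x, ...) {
  cat(sprintf(
    "<observation_window> %s .. %s (%s)\n",
    format(x$start_day), format(x$end_day), x$tz
  ))
  invisible(x)
}

window_days <- function(window) {
  seq(window$start_day, window$end_day, by = "day")
}

#' Bucket timestamps into calendar days
#'
#' @param timestamp A `POSIXct` vector.
#' @param window An [observation_window()]; its timezone drives the bucketing.
#' @return A `Date` vector.
#' @export
tweet_day <- function(timestamp, window) {
  as.Date(lubridate::with_tz(timestamp, tzone = window$tz))
}

tweet_prototype <- function() {
  tibble(
    tweet_id = character(),
    account_id = character(),
    timestamp = lubridate::as_datetime(character()),
    text = character(),
    retweeted_account_id = character(),
    urls = list()
  )
}

parse_timestamp <- function(x) {
  if (is.numeric(x)) {
    return(lubridate::as_datetime(x))
  }
  lubridate::as_datetime(x)
}

#' Read a tweet stream from JSON lines
#'
#' Reads a UTF-8 JSONL file with one tweet record per line. Each record must
#' carry `tweet_id`, `account_id` and `timestamp` (ISO-8601 string or epoch
#' seconds); `text`, `retweeted_account_id` and `urls` are optional. Records
#' timestamped outside `window` (by day, in the window's timezone) are
#' dropped.
#'
#' @param path Path to a JSONL file.
#' @param window Optional [observation_window()]. When supplied, only records
#'   whose day falls inside the window are returned.
#' @param on_malformed What to do with unparseable lines or records missing a
#'   required field: `"skip"` (drop them and warn with a count) or `"error"`.
#'
#' @return A tibble of tweets with columns `tweet_id`, `account_id`,
#'   `timestamp` (POSIXct, UTC storage), `text`, `retweeted_account_id`
#'   (`NA` for original tweets) and `urls` (list column of character vectors).
#' @seealso [write_tweet_stream()]
#' @export
read_tweet_stream <- function(path, window = NULL,
                              on_malformed = c("skip", "error")) {
  on_malformed <- match.arg(on_malformed)
  if (!file.exists(path)) {
    abort(sprintf("cannot read tweet stream: no such file '%s'", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n_bad <- 0L
  records <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[k]], simplifyVector = TRUE),
      error = function(e) NULL
    )
    ok <- !is.null(rec) &&
      all(c("tweet_id", "account_id", "timestamp") %in% names(rec)) &&
      !is.null(rec$tweet_id) && !is.null(rec$account_id) &&
      !is.null(rec$timestamp)
    ts <- if (ok) parse_timestamp(rec$timestamp) else NA
    ok <- ok && length(ts) == 1L && !is.na(ts) && is.finite(as.numeric(ts))
    if (!ok) {
      if (on_malformed == "error") {
        abort(sprintf("malformed tweet record at line %d of '%s'", k, path))
      }
      n_bad <- n_bad + 1L
      next
    }
    records[[k]] <- tibble(
      tweet_id = as.character(rec$tweet_id),
      account_id = as.character(rec$account_id),
      timestamp = ts,
      text = as.character(rec$text %||% ""),
      retweeted_account_id = as.character(
        rec$retweeted_account_id %||% NA_character_
      ),
      urls = list(as.character(unlist(rec$urls %||% character())))
    )
  }
  out <- bind_rows(tweet_prototype(), records)
  if (n_bad > 0L) {
    warn(sprintf("skipped %d malformed line(s) in '%s'", n_bad, path))
  }
  if (!is.null(window)) {
    day <- tweet_day(out$timestamp, window)
    out <- out[day >= window$start_day & day <= window$end_day, , drop = FALSE]
  }
  if (anyDuplicated(out$tweet_id)) {
    warn("duplicate tweet_id values in stream")
  }
  out
}

#' Write a tweet stream as JSON lines
#'
#' Inverse of [read_tweet_stream()]: one JSON object per line, UTF-8, with
#' timestamps serialized as ISO-8601 UTC. A written stream re-read with
#' [read_tweet_stream()] reproduces the input field for field.
#'
#' @param tweets A tweet tibble as returned by [read_tweet_stream()] or
#'   [generate_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tweet_stream <- function(tweets, path) {
  lines <- vapply(seq_len(nrow(tweets)), function(i) {
    rec <- list(
      tweet_id = tweets$tweet_id[[i]],
      account_id = tweets$account_id[[i]],
      timestamp = format(
        lubridate::with_tz(tweets$timestamp[[i]], "UTC"),
        "%Y-%m-%dT%H:%M:%SZ"
      ),
      text = tweets$text[[i]]
    )
    rt <- tweets$retweeted_account_id[[i]]
    if (!is.na(rt)) rec$retweeted_account_id <- rt
    urls <- tweets$urls[[i]]
    if (length(urls)) rec$urls <- urls
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Account activity under attrition
#'
#' A monitored account is considered *active* on a day if at least one tweet
#' from it is observed on that day or any later day of the window; once its
#' last observed tweet passes, it is counted as churned. `active_on_day()`
#' tests a single (account, day) pair; `active_account_days()` counts, for
#' each account, the number of window days on which it is active, which for
#' an account that tweets at all equals `last tweet day - start day + 1`.
#' These counts normalize per-capita tweet rates for attrition.
#'
#' @param tweets A tweet tibble.
#' @param account A single account id.
#' @param day A single `Date`.
#' @param window An [observation_window()].
#' @param accounts Optional character vector of accounts to report on
#'   (defaults to every account in `tweets`); accounts with no tweets in the
#'   window get 0 active days.
#'
#' @return `active_on_day()`: a logical scalar. `active_account_days()`: a
#'   tibble with columns `account_id` and `active_days`.
#' @export
active_on_day <- function(tweets, account, day, window) {
  day <- as.Date(day)
  rows <- tweets[tweets$account_id == account, , drop = FALSE]
  if (nrow(rows) == 0L) {
    return(FALSE)
  }
  days <- tweet_day(rows$timestamp, window)
  days <- days[days >= window$start_day & days <= window$end_day]
  if (length(days) == 0L) {
    return(FALSE)
  }
  day >= window$start_day && day <= window$end_day && any(days >= day)
}

#' @rdname active_on_day
#' @export
active_account_days <- function(tweets, window, accounts = NULL) {
  accounts <- accounts %||% sort(unique(tweets$account_id))
  day <- tweet_day(tweets$timestamp, window)
  keep <- day >= window$start_day & day <= window$end_day
  last_day <- tapply(day[keep], tweets$account_id[keep], max)
  active <- as.integer(
    pmax(0, unclass(last_day) - unclass(window$start_day) + 1)
  )
  lut <- setNames(active, names(last_day))
  tibble(
    account_id = accounts,
    active_days = as.integer(ifelse(
      is.na(lut[accounts]), 0L, lut[accounts]
    ))
  )
}

#' Accounts active on each day of a window
#'
#' Counts, for every day of the window, how many of the given accounts are
#' active on that day in the sense of [active_on_day()]. Used to express
#' daily topical volume as tweets per 15 active accounts.
#'
#' @inheritParams active_on_day
#' @return A tibble with columns `day` and `n_active`.
#' @export
active_accounts_by_day <- function(tweets, window, accounts = NULL) {
  accounts <- accounts %||% sort(unique(tweets$account_id))
  aad <- active_account_days(tweets, window, accounts)
  days <- window_days(window)
  # account active on day d iff its last tweet day >= d, i.e. active_days >=
  # (d - start + 1)
  offs <- as.integer(unclass(days) - unclass(window$start_day) + 1)
  tibble(
    day = days,
    n_active = vapply(
      offs, function(o) sum(aad$active_days >= o), integer(1)
    )
  )
}
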