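default_shorteners <- function() {
  c(
    "bit.ly", "t.co", "ow.ly", "tinyurl.com", "goo.gl", "buff.ly",
    "dlvr.it", "ift.tt", "is.gd", "trib.al", "tiny.cc", "shar.es"
  )
}

# public suffixes with a mandatory third label; a pragmatic short list
second_level_suffixes <- function() {
  c(
    "co.uk", "org.uk", "ac.uk", "gov.uk", "com.au", "net.au", "org.au",
    "co.jp", "co.in", "co.nz", "com.br", "com.mx", "co.za"
  )
}

#' Normalize and classify linked URLs
#'
#' Reduces a URL to its lowercased registered domain
#' (`"https://www.foxnews.com/politics/x"` becomes `"foxnews.com"`) and
#' tags links to twitter.com and to known URL shorteners so that callers
#' can exclude and count them separately. `normalize_domain()` returns the
#' domain strings (`NA` where unparseable); `classify_urls()` returns the
#' full classification.
#'
#' @param urls Character vector of URL-like strings.
#' @param shorteners Character vector of shortener domains; defaults to a
#'   shipped list (bit.ly, t.co, ow.ly, tinyurl.com, ...).
#' @return `classify_urls()`: a tibble with `url`, `domain` and `kind`, the
#'   latter one of `"domain"`, `"twitter"`, `"shortener"`, `"invalid"`.
#' @export
classify_urls <- function(urls, shorteners = default_shorteners()) {
  host <- tolower(urls)
  host <- sub("^[a-z][a-z0-9+.-]*://", "", host)
  host <- sub("^//", "", host)
  host <- sub("[/?#:].*$", "", host)
  host <- sub("^www[0-9]*\\.", "", host)
  ok <- grepl("^[a-z0-9][a-z0-9.-]*\\.[a-z]{2,}$", host)
  domain <- rep(NA_character_, length(urls))
  if (any(ok)) {
    domain[ok] <- vapply(host[ok], registered_domain, character(1))
  }
  kind <- dplyr::case_when(
    is.na(domain) ~ "invalid",
    domain == "twitter.com" ~ "twitter",
    domain %in% shorteners ~ "shortener",
    TRUE ~ "domain"
  )
  tibble(url = urls, domain = domain, kind = kind)
}

#' @rdname classify_urls
#' @export
normalize_domain <- function(urls, shorteners = default_shorteners()) {
  classify_urls(urls, shorteners)$domain
}

registered_domain <- function(host) {
  parts <- strsplit(host, ".", fixed = TRUE)[[1]]
  np <- length(parts)
  if (np <= 2L) {
    return(host)
  }
  tail2 <- paste(parts[np - 1L], parts[np], sep = ".")
  if (tail2 %in% second_level_suffixes() && np >= 3L) {
    return(paste(parts[np - 2L], tail2, sep = "."))
  }
  tail2
}

#' Community-by-domain link frequency matrix
#'
#' Tallies the external domains linked by each community's tweets and forms
#' the row-stochastic frequency matrix whose `(i, j)` entry is the fraction
#' of community `i`'s qualifying links that point to domain `j`. Links to
#' twitter.com and to URL shorteners are excluded and counted separately,
#' as are domains whose total share count across all communities falls
#' below `min_total` (set `per_community = TRUE` to instead keep a domain
#' when some single community shares it at least `min_total` times).
#'
#' @param tweets A tweet tibble with a `urls` list column.
#' @param membership A tibble mapping `account_id` to `community` (each
#'   tweeting account to at most one community); tweets from unassigned
#'   accounts are dropped.
#' @param min_total Retention threshold on domain share counts (default 10).
#' @param per_community Apply the threshold per community instead of to the
#'   all-communities total.
#' @param shorteners Shortener list passed to [classify_urls()].
#'
#' @return A `domain_matrix` object: the frequency `matrix` (communities by
#'   domains; all-zero rows are flagged in `empty_communities`), the raw
#'   `counts`, and an `accounting` tibble in which
#'   `total = twitter + shortened + retained` and `retained` further splits
#'   into links to kept and discarded (sub-threshold) domains.
#' @export
build_domain_matrix <- function(tweets, membership, min_total = 10L,
                                per_community = FALSE,
                                shorteners = default_shorteners()) {
  links <- tweets |>
    select("tweet_id", "account_id", "urls") |>
    tidyr::unnest_longer("urls", values_to = "url") |>
    inner_join(membership, by = "account_id")
  cls <- classify_urls(links$url, shorteners)
  links$domain <- cls$domain
  links$kind <- cls$kind
  n_total <- nrow(links)
  n_twitter <- sum(links$kind == "twitter")
  n_short <- sum(links$kind == "shortener")
  retained <- links |> filter(.data$kind %in% c("domain", "invalid"))
  usable <- retained |> filter(.data$kind == "domain")
  counts <- usable |>
    count(.data$community, .data$domain, name = "n_links")
  totals <- counts |>
    group_by(.data$domain) |>
    summarise(
      total = sum(.data$n_links),
      max_comm = max(.data$n_links),
      .groups = "drop"
    )
  kept_domains <- if (per_community) {
    totals$domain[totals$max_comm >= min_total]
  } else {
    totals$domain[totals$total >= min_total]
  }
  communities <- sort(unique(membership$community))
  kept_domains <- sort(kept_domains)
  mat <- matrix(
    0,
    nrow = length(communities), ncol = length(kept_domains),
    dimnames = list(as.character(communities), kept_domains)
  )
  kc <- counts |> filter(.data$domain %in% kept_domains)
  if (nrow(kc)) {
    mat[cbind(
      match(as.character(kc$community), rownames(mat)),
      match(kc$domain, colnames(mat))
    )] <- kc$n_links
  }
  rs <- rowSums(mat)
  empty <- rownames(mat)[rs == 0]
  mat[rs > 0, ] <- mat[rs > 0, , drop = FALSE] / rs[rs > 0]
  if (length(empty)) {
    warn(sprintf(
      "%d communit%s with no retained links above threshold",
      length(empty), if (length(empty) == 1) "y" else "ies"
    ))
  }
  accounting <- tibble(
    total = n_total,
    twitter = n_twitter,
    shortened = n_short,
    retained = nrow(retained),
    in_matrix = sum(usable$domain %in% kept_domains),
    distinct_domains = dplyr::n_distinct(usable$domain),
    kept_domains = length(kept_domains)
  )
  structure(
    list(
      matrix = mat, counts = counts, accounting = accounting,
      empty_communities = empty, min_total = min_total,
      per_community = per_community
    ),
    class = "domain_matrix"
  )
}

#' Link accounting identity
#'
#' Splits a link total into twitter, shortened and retained links:
#' `retained = total - twitter - shortened`. The same identity is computed
#' by [build_domain_matrix()] from raw tweets; this helper applies it to
#' already-tallied totals.
#'
#' @param total,twitter,shortened Link counts.
#' @return A one-row tibble with the three inputs and `retained`.
#' @export
link_accounting <- function(total, twitter, shortened) {
  if (twitter + shortened > total) abort("parts exceed the total")
  tibble(
    total = total, twitter = twitter, shortened = shortened,
    retained = total - twitter - shortened
  )
}

#' @export
print.domain_matrix <- function(x, ...) {
  cat(sprintf(
    "<domain_matrix> %d communities x %d domains (threshold %d, %s)\n",
    nrow(x$matrix), ncol(x$matrix), x$min_total,
    if (x$per_community) "per community" else "total"
  ))
  invisible(x)
}

#' @export
tidy.domain_matrix <- function(x, ...) {
  as_tibble(x$matrix, rownames = "community") |>
    tidyr::pivot_longer(
      -"community",
      names_to = "domain", values_to = "fraction"
    )
}

#' @export
glance.domain_matrix <- function(x, ...) x$accounting
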