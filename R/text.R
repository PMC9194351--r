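the_stopwords <- new.env(parent = emptyenv())

#' Shipped English stopword list
#'
#' @return Character vector of lowercase stopwords used by [clean_text()].
#' @export
default_stopwords <- function() {
  if (is.null(the_stopwords$words)) {
    path <- system.file("extdata", "stopwords_en.txt",
      package = "sentinelnet"
    )
    the_stopwords$words <- readLines(path, encoding = "UTF-8")
  }
  the_stopwords$words
}

#' Clean tweet text into tokens
#'
#' Deterministic cleaning used before building trigram vectors: lowercase;
#' strip URLs (`http(s)://...`, `t.co/...`, `www....`) and `@` mentions;
#' split on anything that is not a letter, digit or internal apostrophe;
#' drop stopwords from a fixed shipped English list.
#'
#' @param text Character vector of raw tweet texts.
#' @param stopwords Stopword vector; defaults to the shipped list.
#' @return A list of character token vectors, one per input text (possibly
#'   empty).
#' @examples
#' clean_text("Check https://x.co @bob THE masks")
#' @export
clean_text <- function(text, stopwords = default_stopwords()) {
  x <- stringr::str_to_lower(text)
  x <- stringr::str_replace_all(
    x, "(https?://\\S+)|(\\bt\\.co/\\S+)|(\\bwww\\.\\S+)", " "
  )
  x <- stringr::str_replace_all(x, "@\\w+", " ")
  toks <- stringr::str_extract_all(x, "[a-z0-9]+(?:'[a-z0-9]+)*")
  lapply(toks, function(tt) tt[!tt %in% stopwords])
}

#' Trigram count vector for a document of tweets
#'
#' Counts consecutive word triples within each tweet's token list and sums
#' the counts over the document. Trigrams never span tweet boundaries, and
#' tweets with fewer than three tokens contribute nothing.
#'
#' @param token_lists A list of token vectors (one per tweet), as returned
#'   by [clean_text()].
#' @return A named numeric vector: trigram (`"a b c"`) to count. Length 0
#'   for an empty document.
#' @export
trigram_vector <- function(token_lists) {
  grams <- unlist(lapply(token_lists, function(tt) {
    n <- length(tt)
    if (n < 3L) {
      return(character())
    }
    paste(tt[1:(n - 2)], tt[2:(n - 1)], tt[3:n])
  }))
  if (!length(grams)) {
    return(setNames(numeric(), character()))
  }
  tab <- table(grams)
  setNames(as.numeric(tab), names(tab))
}

#' Cosine similarity of sparse count vectors
#'
#' Standard cosine similarity on named count vectors; because counts are
#' nonnegative the value lies in `[0, 1]`. When either vector is all zero
#' (or empty) the similarity is defined as 0.
#'
#' @param v1,v2 Named numeric vectors of nonnegative counts.
#' @return A number in `[0, 1]`.
#' @export
cosine_similarity <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    return(0)
  }
  shared <- intersect(names(v1), names(v2))
  if (!length(shared)) {
    return(0)
  }
  sum(v1[shared] * v2[shared]) / (n1 * n2)
}

#' Jaccard similarity of trigram supports
#'
#' Set-overlap of the trigrams present in two vectors; used to match
#' near-duplicate tweets across clusters when attributing bursts.
#'
#' @inheritParams cosine_similarity
#' @return A number in `[0, 1]`; 0 when both are empty.
#' @export
trigram_jaccard <- function(v1, v2) {
  a <- names(v1)[v1 > 0]
  b <- names(v2)[v2 > 0]
  u <- union(a, b)
  if (!length(u)) {
    return(0)
  }
  length(intersect(a, b)) / length(u)
}
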