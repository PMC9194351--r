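# independent oracle implementations used to check the package's fast paths

# all set partitions of 1..n as lists of integer label vectors
all_partitions <- function(n) {
  if (n == 1L) {
    return(list(1L))
  }
  out <- list()
  for (p in all_partitions(n - 1L)) {
    k <- max(p)
    for (lab in seq_len(k + 1L)) out[[length(out) + 1L]] <- c(p, lab)
  }
  out
}

# direct double-sum evaluation of directed modularity on an adjacency matrix
# (A[i, j] = times j retweeted i)
oracle_modularity <- function(a, labels) {
  w <- sum(a)
  win <- rowSums(a)
  wout <- colSums(a)
  q <- 0
  n <- nrow(a)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j]) {
        q <- q + a[i, j] - unname(win[i] * wout[j]) / w
      }
    }
  }
  q / w
}

# definitional krippendorff alpha: explicit enumeration of code pairs
oracle_krippendorff <- function(m) {
  m <- as.matrix(m)
  mode(m) <- "character"
  keep <- rowSums(!is.na(m)) >= 2
  m <- m[keep, , drop = FALSE]
  d_o <- 0
  margins <- c()
  for (u in seq_len(nrow(m))) {
    v <- m[u, ][!is.na(m[u, ])]
    mu <- length(v)
    for (a in seq_len(mu)) {
      for (b in seq_len(mu)) {
        if (a != b) d_o <- d_o + as.integer(v[a] != v[b]) / (mu - 1)
      }
    }
    # every code instance carries total pairing weight 1
    margins <- c(margins, v)
  }
  tab <- table(margins)
  n_tot <- sum(tab)
  d_e <- (n_tot^2 - sum(tab^2)) / (n_tot - 1)
  1 - d_o / d_e
}

# pair-enumeration rand index + permutation null for w12
oracle_rand_perm <- function(v1, v2, n_perm = 2000, seed = 1) {
  n <- length(v1)
  same1 <- outer(v1, v1, "==")[upper.tri(diag(n))]
  same2 <- outer(v2, v2, "==")[upper.tri(diag(n))]
  rand <- mean(same1 == same2)
  w12 <- sum(same1 & same2)
  perms <- withr::with_seed(seed, replicate(n_perm, {
    p <- v2[sample.int(n)]
    sum(same1 & outer(p, p, "==")[upper.tri(diag(n))])
  }))
  list(
    rand = rand, w12 = w12,
    mean = mean(perms), sd = sd(perms),
    z = (w12 - mean(perms)) / sd(perms)
  )
}

# rule-by-rule reference silhouette for a 1-d clustering
oracle_silhouette <- function(x, labels) {
  n <- length(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) {
      s[i] <- 0
      next
    }
    a <- mean(abs(x[i] - x[setdiff(own, i)]))
    b <- min(vapply(
      setdiff(unique(labels), labels[i]),
      function(l) mean(abs(x[i] - x[labels == l])),
      numeric(1)
    ))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# regex-free substring scan
oracle_substring_match <- function(texts, substrings) {
  vapply(texts, function(tx) {
    tx <- tolower(tx)
    any(vapply(
      substrings,
      function(s) {
        nc <- nchar(s)
        if (nc > nchar(tx)) {
          return(FALSE)
        }
        any(vapply(
          seq_len(nchar(tx) - nc + 1L),
          function(k) substr(tx, k, k + nc - 1L) == s,
          logical(1)
        ))
      },
      logical(1)
    ))
  }, logical(1), USE.NAMES = FALSE)
}

# hand chi-square from definition
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}
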