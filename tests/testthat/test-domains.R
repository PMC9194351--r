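test_that("url normalization and tagging follow the stated rules", {
  cls <- classify_urls(c(
    "https://www.foxnews.com/politics/x",
    "http://WWW.Example.co.uk/a?b=1",
    "https://bit.ly/abc",
    "https://twitter.com/u/status/1",
    "not a url",
    "https://sub.motherjones.com/2020"
  ))
  expect_equal(cls$domain[1], "foxnews.com")
  expect_equal(cls$domain[2], "example.co.uk")
  expect_equal(cls$kind[3], "shortener")
  expect_equal(cls$kind[4], "twitter")
  expect_true(is.na(cls$domain[5]) && cls$kind[5] == "invalid")
  expect_equal(cls$domain[6], "motherjones.com")
  expect_equal(normalize_domain("https://www.foxnews.com/x"), "foxnews.com")
})

domain_tweets <- function(spec) {
  # spec: tibble(account_id, url)
  make_tweets(
    account_id = spec$account_id,
    urls = lapply(spec$url, function(u) if (is.na(u)) character() else u)
  )
}

test_that("domain matrix applies the retention threshold and renormalizes", {
  spec <- tibble::tibble(
    account_id = "a1",
    url = c(
      rep("https://a.com/x", 12),
      rep("https://b.com/y", 3)
    )
  )
  memb <- tibble::tibble(account_id = "a1", community = 1L)
  dm <- build_domain_matrix(domain_tweets(spec), memb, min_total = 10)
  expect_equal(colnames(dm$matrix), "a.com")
  expect_equal(unname(dm$matrix[1, 1]), 1.0)

  # two communities each sharing only its own qualifying domain
  spec2 <- tibble::tibble(
    account_id = rep(c("a1", "b1"), each = 12),
    url = rep(c("https://a.com/x", "https://b.com/y"), each = 12)
  )
  memb2 <- tibble::tibble(account_id = c("a1", "b1"), community = 1:2)
  dm2 <- build_domain_matrix(domain_tweets(spec2), memb2, min_total = 10)
  expect_equal(
    unname(dm2$matrix),
    matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  )

  # per-community variant keeps a domain one community shares enough
  dm3 <- build_domain_matrix(domain_tweets(spec2), memb2,
    min_total = 10, per_community = TRUE
  )
  expect_setequal(colnames(dm3$matrix), c("a.com", "b.com"))
})

test_that("link accounting identity: total = twitter + shortened + retained", {
  spec <- tibble::tibble(
    account_id = "a1",
    url = c(
      rep("https://twitter.com/s/1", 4),
      rep("https://bit.ly/zz", 3),
      rep("https://a.com/x", 11),
      "https://ow.ly/q"
    )
  )
  memb <- tibble::tibble(account_id = "a1", community = 1L)
  dm <- build_domain_matrix(domain_tweets(spec), memb)
  acc <- dm$accounting
  expect_equal(acc$total, 19L)
  expect_equal(acc$twitter, 4L)
  expect_equal(acc$shortened, 4L)
  expect_equal(acc$retained, 11L)
  expect_equal(acc$total, acc$twitter + acc$shortened + acc$retained)

  la <- link_accounting(total = 100, twitter = 30, shortened = 20)
  expect_equal(la$retained, 50)
  expect_error(link_accounting(10, 8, 5), "exceed")

  # a community with no retained links is flagged
  spec0 <- tibble::tibble(
    account_id = c(rep("a1", 12), "b1"),
    url = c(rep("https://a.com/x", 12), "https://twitter.com/only")
  )
  memb0 <- tibble::tibble(account_id = c("a1", "b1"), community = 1:2)
  expect_warning(
    dm0 <- build_domain_matrix(domain_tweets(spec0), memb0),
    "no retained links"
  )
  expect_equal(dm0$empty_communities, "2")
  expect_equal(sum(dm0$matrix[2, ]), 0)
})

test_that("first principal component scores match hand eigen-decomposition", {
  m <- matrix(c(1, 0, 0, 1), 2,
    byrow = TRUE,
    dimnames = list(c("c1", "c2"), c("a.com", "b.com"))
  )
  sc <- pca_first_component(m)
  expect_equal(sort(sc$scores$score), c(-1, 1) / sqrt(2))
  expect_equal(sum(sc$scores$score), 0)

  # identical rows: centered matrix is rank 0
  flat <- matrix(0.5, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(sc0 <- pca_first_component(flat), "same domain profile")
  expect_equal(sc0$scores$score, rep(0, 3))

  # anchored sign convention
  sc_a <- pca_first_component(m, anchor = "a.com")
  expect_gt(
    sc_a$loadings$loading[sc_a$loadings$domain == "a.com"], 0
  )
  sc_b <- pca_first_component(m, anchor = "b.com")
  expect_gt(
    sc_b$loadings$loading[sc_b$loadings$domain == "b.com"], 0
  )
  expect_equal(sc_a$scores$score, -sc_b$scores$score)
})

test_that("planted domain poles separate with the correct signs", {
  corp <- generate_corpus(synthetic_config(days = 6, seed = 17))
  dm <- build_domain_matrix(corp$tweets, corp$truth$membership)
  sc <- pca_first_component(dm, anchor = synthetic_pole_domains("right")[1])
  joined <- dplyr::inner_join(
    sc$scores |> dplyr::mutate(community = as.integer(community)),
    corp$truth$poles,
    by = "community"
  )
  expect_true(all(joined$score[joined$pole == "right"] > 0))
  expect_true(all(joined$score[joined$pole == "left"] < 0))

  # invariance to row and column permutation (up to anchored sign)
  m <- dm$matrix
  perm <- withr::with_seed(2, list(
    r = sample(nrow(m)), c = sample(ncol(m))
  ))
  sc_p <- pca_first_component(
    m[perm$r, perm$c],
    anchor = synthetic_pole_domains("right")[1]
  )
  ord <- match(sc$scores$community, sc_p$scores$community)
  expect_equal(sc_p$scores$score[ord], sc$scores$score, tolerance = 1e-8)
})

test_that("score clustering matches the silhouette oracle and stays contiguous", {
  x <- setNames(c(0, 0.1, 10, 10.1), paste0("c", 1:4))
  cl <- cluster_scores(x, max_k = 3, k = 2)
  expect_equal(
    sort(unname(tapply(cl$clusters$cluster, cl$clusters$community, unique))),
    c(1, 1, 2, 2)[order(paste0("c", 1:4))]
  )
  expect_equal(cl$clusters$cluster, c(1, 1, 2, 2))
  sil_oracle <- oracle_silhouette(unname(x), c(1, 1, 2, 2))
  expect_equal(cl$silhouette, sil_oracle, tolerance = 1e-12)
  expect_gt(cl$silhouette, 0.97)

  # three well-separated triplets are recovered at k = 3
  y <- setNames(
    c(0, 0.2, 0.4, 50, 50.3, 50.6, 100, 100.1, 100.4),
    paste0("c", 1:9)
  )
  cl3 <- cluster_scores(y, max_k = 5)
  expect_equal(cl3$k, 3L)
  expect_equal(cl3$clusters$cluster, rep(1:3, each = 3))

  # silhouette-optimal vs forced cut are both reported
  expect_true(cl3$silhouettes$k[which.max(cl3$silhouettes$silhouette)] == 3)
  forced <- cluster_scores(y, max_k = 5, k = 2)
  expect_true(forced$forced)
  expect_equal(forced$k, 2L)

  # degenerate: all scores equal
  expect_warning(
    flat <- cluster_scores(setNames(rep(1, 4), paste0("c", 1:4))),
    "identical"
  )
  expect_equal(flat$k, 1L)

  # clusters on the line are contiguous in score order
  withr::with_seed(33, {
    for (rep in 1:5) {
      z <- setNames(runif(12), sprintf("c%02d", 1:12))
      for (linkage in c("centroid", "average")) {
        cc <- cluster_scores(z, max_k = 4, linkage = linkage)
        ord <- order(cc$clusters$score)
        runs <- rle(cc$clusters$cluster[ord])
        expect_equal(
          length(runs$values), length(unique(cc$clusters$cluster))
        )
      }
    }
  })
})

test_that("removing a dominant domain shifts mainly its communities", {
  m <- rbind(
    c(0.9, 0.1, 0),
    c(0.8, 0.2, 0),
    c(0.27, 0.03, 0.7),
    c(0.03, 0.27, 0.7),
    c(0.1, 0.9, 0),
    c(0.2, 0.8, 0)
  )
  dimnames(m) <- list(paste0("c", 1:6), c("d1", "d2", "X"))
  base <- pca_first_component(m, anchor = "d1")
  m2 <- m[, colnames(m) != "X"]
  m2 <- m2 / rowSums(m2)
  after <- pca_first_component(m2, anchor = "d1")
  affected <- c("c3", "c4")
  plain <- setdiff(rownames(m), affected)
  d_base <- setNames(base$scores$score, base$scores$community)
  d_after <- setNames(after$scores$score, after$scores$community)
  # unaffected communities keep their score ordering
  expect_equal(order(d_base[plain]), order(d_after[plain]))
  # affected communities move more than any unaffected one
  expect_gt(
    min(abs(d_after[affected] - d_base[affected])),
    max(abs(d_after[plain] - d_base[plain]))
  )
})

test_that("bias-category join reports distributions and ordinal correlation", {
  sc <- list(
    loadings = tibble::tibble(
      domain = c("l.com", "r.com"),
      loading = c(-1, 1)
    )
  )
  class(sc) <- "domain_score"
  bias <- tibble::tibble(
    domain = c("l.com", "r.com"),
    category = c("Left", "Right")
  )
  bj <- join_bias_categories(sc, bias)
  expect_equal(bj$correlation, 1.0)
  expect_equal(bj$match_rate, 1.0)

  # loadings independent of category: correlation near zero
  political_levels <- c(
    "Left" = 1, "Center Left" = 2, "Center" = 3,
    "Center Right" = 4, "Right" = 5
  )
  withr::with_seed(10, {
    nbig <- 10000
    scbig <- list(loadings = tibble::tibble(
      domain = sprintf("d%05d.com", 1:nbig),
      loading = rnorm(nbig)
    ))
    class(scbig) <- "domain_score"
    biasbig <- tibble::tibble(
      domain = scbig$loadings$domain,
      category = sample(names(political_levels), nbig, TRUE)
    )
    bjbig <- join_bias_categories(scbig, biasbig)
    expect_lt(abs(bjbig$correlation), 0.05)

    # permuting category labels permutes per-category distributions
    permmap <- sample(names(political_levels))
    names(permmap) <- names(political_levels)
    bias_perm <- biasbig |>
      dplyr::mutate(category = unname(permmap[category]))
    bj_perm <- join_bias_categories(scbig, bias_perm)
    a <- bjbig$categories |> dplyr::arrange(category)
    b <- bj_perm$categories |>
      dplyr::mutate(category = names(permmap)[match(category, permmap)]) |>
      dplyr::arrange(category)
    expect_equal(a$n, b$n)
    expect_equal(a$mean_loading, b$mean_loading)
  })

  # no overlap: undefined
  none <- join_bias_categories(
    sc, tibble::tibble(domain = "zz.com", category = "Left")
  ) |> suppressWarnings()
  expect_true(is.na(none$correlation))
})
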