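#' Linked domain score: first principal component of domain preferences
#'
#' Projects communities onto the first principal component of the
#' community-by-domain link frequency matrix, yielding a scalar "linked
#' domain score" per community together with a loading per domain. Columns
#' are mean-centered but not variance-scaled: the rows are compositions on
#' a common scale and unit-variance scaling would inflate rare domains.
#' Because a principal axis is defined only up to sign, the orientation is
#' fixed by an anchor: the loading of `anchor` (when supplied and present)
#' is forced positive, otherwise the largest-magnitude loading is. Scoring
#' the conservative pole positive, as in media-preference analyses, is a
#' matter of anchoring on, say, `"foxnews.com"`.
#'
#' @param dfm A `domain_matrix` from [build_domain_matrix()], or a plain
#'   numeric matrix (communities by domains).
#' @param anchor Optional domain name fixing the sign convention.
#' @return A `domain_score` object with tibbles `scores` (`community`,
#'   `score`; zero mean across communities) and `loadings` (`domain`,
#'   `loading`), plus the share of variance carried by the first component.
#'   A rank-0 centered matrix (all rows identical) yields all-zero scores
#'   and a warning.
#' @export
pca_first_component <- function(dfm, anchor = NULL) {
  mat <- if (inherits(dfm, "domain_matrix")) dfm$matrix else as.matrix(dfm)
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    abort("need at least 2 communities and 2 domains")
  }
  centered <- scale(mat, center = TRUE, scale = FALSE)
  sv <- svd(centered)
  degenerate <- sv$d[1] < 1e-12
  if (degenerate) {
    warn("all communities share the same domain profile; scores are 0")
    scores <- rep(0, nrow(mat))
    loadings <- rep(0, ncol(mat))
    var_share <- 0
  } else {
    loadings <- sv$v[, 1]
    scores <- centered %*% loadings
    flip <- if (!is.null(anchor) && anchor %in% colnames(mat)) {
      sign(loadings[match(anchor, colnames(mat))])
    } else {
      sign(loadings[which.max(abs(loadings))])
    }
    if (flip < 0) {
      loadings <- -loadings
      scores <- -scores
    }
    var_share <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(
    list(
      scores = tibble(
        community = rownames(mat) %||% as.character(seq_len(nrow(mat))),
        score = as.numeric(scores)
      ),
      loadings = tibble(
        domain = colnames(mat) %||% as.character(seq_len(ncol(mat))),
        loading = as.numeric(loadings)
      ),
      var_share = var_share,
      anchor = anchor,
      degenerate = degenerate
    ),
    class = "domain_score"
  )
}

#' @export
print.domain_score <- function(x, ...) {
  cat(sprintf(
    "<domain_score> %d communities, %d domains; PC1 carries %.1f%% variance\n",
    nrow(x$scores), nrow(x$loadings), 100 * x$var_share
  ))
  invisible(x)
}

#' @export
tidy.domain_score <- function(x, ...) x$scores

#' @export
glance.domain_score <- function(x, ...) {
  tibble(
    n_communities = nrow(x$scores),
    n_domains = nrow(x$loadings),
    var_share = x$var_share,
    degenerate = x$degenerate
  )
}

#' Cluster communities on their linked domain scores
#'
#' Agglomerative clustering of the one-dimensional linked domain scores,
#' with centroid linkage by default (average linkage behind the `linkage`
#' flag; on one-dimensional data the two differ only marginally).
#' Silhouette scores are computed for every cut from 2 to `max_k`; the
#' silhouette-optimal cut is reported, and a different cut can be forced
#' through `k` when domain knowledge warrants it. Cluster labels are
#' ordered by increasing mean score, so label 1 is the most negative pole.
#'
#' @param scores A `domain_score` object or a named numeric vector of
#'   scores.
#' @param max_k Largest cut to evaluate (default `min(8, n - 1)`).
#' @param k Optional forced number of clusters; default picks the best
#'   silhouette.
#' @param linkage `"centroid"` (default) or `"average"`.
#' @return A `score_clusters` object: `clusters` tibble (`community`,
#'   `score`, `cluster`), `silhouettes` tibble (`k`, `silhouette`), chosen
#'   `k`, achieved `silhouette`, and the `hclust` tree.
#' @export
cluster_scores <- function(scores, max_k = NULL, k = NULL,
                           linkage = c("centroid", "average")) {
  linkage <- match.arg(linkage)
  if (inherits(scores, "domain_score")) {
    x <- setNames(scores$scores$score, scores$scores$community)
  } else {
    x <- scores
    if (is.null(names(x))) names(x) <- as.character(seq_along(x))
  }
  n <- length(x)
  if (n < 3L) abort("need at least 3 communities to cluster")
  max_k <- max_k %||% min(8L, n - 1L)
  max_k <- min(max_k, n - 1L)
  d <- dist(x)
  if (all(d == 0)) {
    warn("all scores identical; returning a single degenerate cluster")
    return(structure(
      list(
        clusters = tibble(community = names(x), score = x, cluster = 1L),
        silhouettes = tibble(k = integer(), silhouette = numeric()),
        k = 1L, silhouette = NA_real_, forced = FALSE, tree = NULL,
        linkage = linkage
      ),
      class = "score_clusters"
    ))
  }
  tree <- if (linkage == "centroid") {
    hclust(d^2, method = "centroid")
  } else {
    hclust(d, method = "average")
  }
  sil <- purrr::map_dfr(2:max_k, function(kk) {
    cut <- cutree(tree, k = kk)
    if (length(unique(cut)) < 2L) {
      return(tibble(k = kk, silhouette = NA_real_))
    }
    s <- cluster::silhouette(cut, d)
    tibble(k = kk, silhouette = mean(s[, "sil_width"]))
  })
  chosen <- if (!is.null(k)) {
    as.integer(k)
  } else {
    sil$k[which.max(sil$silhouette)]
  }
  cut <- cutree(tree, k = chosen)
  # relabel by increasing mean score
  means <- tapply(x, cut, mean)
  relab <- match(cut, as.integer(names(sort(means))))
  structure(
    list(
      clusters = tibble(
        community = names(x), score = as.numeric(x), cluster = relab
      ),
      silhouettes = sil,
      k = chosen,
      silhouette = sil$silhouette[match(chosen, sil$k)],
      forced = !is.null(k),
      tree = tree,
      linkage = linkage
    ),
    class = "score_clusters"
  )
}

#' @export
print.score_clusters <- function(x, ...) {
  cat(sprintf(
    "<score_clusters> k = %d (%s linkage%s), silhouette %.3f\n",
    x$k, x$linkage, if (x$forced) ", forced" else "",
    if (is.na(x$silhouette)) NA else x$silhouette
  ))
  invisible(x)
}

#' @export
tidy.score_clusters <- function(x, ...) x$clusters

#' @export
glance.score_clusters <- function(x, ...) {
  tibble(
    k = x$k, silhouette = x$silhouette, forced = x$forced,
    linkage = x$linkage
  )
}

political_category_levels <- function() {
  c(
    "Left" = 1, "Center Left" = 2, "Center" = 3,
    "Center Right" = 4, "Right" = 5
  )
}

#' Join media-bias categories onto domain loadings
#'
#' Groups first-component domain loadings by the categories of a
#' user-supplied media-bias table (MBFC-style: Left, Center Left, Center,
#' Center Right, Right, Pro Science, Questionable, Conspiracy, Satire) and
#' computes the Pearson correlation between loading and ordinal political
#' tilt (Left = 1 ... Right = 5) over the five political categories.
#'
#' @param score A `domain_score` object.
#' @param bias_table A tibble/data frame with columns `domain` and
#'   `category`.
#' @return A `bias_join` object: `domains` (matched domains with loading
#'   and category), `categories` (per-category loading summaries),
#'   `correlation` (`NA` when fewer than 3 politically categorized domains
#'   match) and `match_rate`.
#' @export
join_bias_categories <- function(score, bias_table) {
  bias_table <- as_tibble(bias_table)
  matched <- score$loadings |>
    inner_join(bias_table, by = "domain")
  match_rate <- nrow(matched) / nrow(score$loadings)
  categories <- matched |>
    group_by(.data$category) |>
    summarise(
      n = n(),
      mean_loading = mean(.data$loading),
      median_loading = median(.data$loading),
      .groups = "drop"
    )
  ord <- political_category_levels()
  pol <- matched |> filter(.data$category %in% names(ord))
  correlation <- if (nrow(pol) >= 3L && sd(pol$loading) > 0 &&
    length(unique(pol$category)) > 1L) {
    cor(pol$loading, ord[pol$category])
  } else if (nrow(pol) == 2L && sd(pol$loading) > 0 &&
    length(unique(pol$category)) == 2L) {
    cor(pol$loading, ord[pol$category])
  } else {
    NA_real_
  }
  if (is.na(correlation) && nrow(pol) < 2L) {
    warn("too few politically categorized domains; correlation undefined")
  }
  structure(
    list(
      domains = matched, categories = categories,
      correlation = correlation, match_rate = match_rate
    ),
    class = "bias_join"
  )
}

#' @export
print.bias_join <- function(x, ...) {
  cat(sprintf(
    "<bias_join> %.0f%% of domains matched; ordinal correlation %s\n",
    100 * x$match_rate,
    if (is.na(x$correlation)) "NA" else sprintf("%.2f", x$correlation)
  ))
  invisible(x)
}
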