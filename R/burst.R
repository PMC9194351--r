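#' Burst score of a similarity series
#'
#' The burst score standardizes the day's inter-cluster similarity against
#' its own history:
#' \deqn{H(A,B,t) = \frac{s_t - \mathrm{mean}_{\tau<t}\{s_\tau\}}
#'   {\mathrm{SD}_{\tau<t}\{s_\tau\}},}
#' with mean and sample standard deviation (`ddof = 1` by default) taken
#' over *all* observed days strictly before `t` — an expanding, not
#' rolling, window, so the baseline period seeds the history. `H` is
#' undefined (`NA`) while fewer than `burn_in` prior days have been
#' observed, and also when the historical SD is zero (never `Inf`).
#'
#' @param series A `similarity_series` tibble ([cluster_similarity()]), or
#'   any tibble with `day` and `similarity` (optionally grouped by
#'   `cluster_a`/`cluster_b`).
#' @param burn_in Minimum number of prior observed days (default 7).
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"`.
#' @return The input with a `burst` column appended.
#' @export
burst_scores <- function(series, burn_in = 7L,
                         sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  key <- intersect(c("cluster_a", "cluster_b"), names(series))
  series |>
    group_by(across(dplyr::all_of(key))) |>
    arrange(.data$day, .by_group = TRUE) |>
    mutate(burst = expanding_z(.data$similarity, burn_in, sd_type)) |>
    ungroup()
}

expanding_z <- function(x, burn_in, sd_type = "sample") {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    hist <- x[seq_len(t - 1L)]
    hist <- hist[!is.na(hist)]
    if (is.na(x[t]) || length(hist) < max(burn_in, 2L)) next
    s <- sd(hist)
    if (sd_type == "population") {
      s <- s * sqrt((length(hist) - 1) / length(hist))
    }
    if (!is.finite(s) || s == 0) next
    out[t] <- (x[t] - mean(hist)) / s
  }
  out
}

#' Flag burst days
#'
#' Flags the days whose burst score reaches `threshold` (default 2). The
#' first `burn_in` days of the series establish the baseline and are never
#' flagged (their score is undefined anyway, see [burst_scores()]).
#'
#' @inheritParams burst_scores
#' @param threshold Flagging threshold on `H` (default 2).
#' @return A `burst_flags` tibble: `day`, `cluster_a`, `cluster_b`,
#'   `similarity`, `burst`; zero rows when nothing is flagged.
#' @export
flag_bursts <- function(series, threshold = 2, burn_in = 7L,
                        sd_type = c("sample", "population")) {
  scored <- burst_scores(series, burn_in, match.arg(sd_type))
  out <- scored |>
    filter(!is.na(.data$burst), .data$burst >= threshold) |>
    arrange(.data$day)
  class(out) <- c("burst_flags", class(out))
  out
}

#' Augmented Dickey-Fuller stationarity check
#'
#' The burst score presumes the similarity series is stationary around a
#' constant level. This check runs the Dickey-Fuller regression with a
#' constant and zero lagged differences,
#' \eqn{\Delta s_t = \alpha + \rho s_{t-1} + \varepsilon_t}, and tests
#' \eqn{\rho = 0} (unit root) against \eqn{\rho < 0} (stationary). The
#' null distribution of the t-statistic is nonstandard; the p-value is
#' obtained from a seeded Monte-Carlo simulation of driftless random walks
#' of the same length. This is a logged diagnostic gate, not a hard stop.
#'
#' @param x Numeric series (at least 10 observations).
#' @param level Significance level for the verdict (default 0.05).
#' @param n_sim Null-simulation size (default 4000).
#' @param seed Seed for the null simulation (fixed by default so repeated
#'   checks agree).
#' @return A one-row tibble with `statistic`, `p_value`, `verdict`
#'   (`"stationary"`, `"non-stationary"` or `"degenerate"`), and `n`.
#' @export
adf_check <- function(x, level = 0.05, n_sim = 4000L, seed = 1L) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 10L) abort("need at least 10 observations")
  if (sd(x) == 0) {
    return(tibble(
      statistic = NA_real_, p_value = NA_real_,
      verdict = "degenerate", n = n
    ))
  }
  stat <- df_tau(x)
  null <- withr::with_seed(as.integer(seed), {
    steps <- matrix(rnorm(n_sim * n), nrow = n)
    walks <- apply(steps, 2, cumsum)
    apply(walks, 2, df_tau)
  })
  p <- mean(null <= stat)
  tibble(
    statistic = stat,
    p_value = p,
    verdict = if (p < level) "stationary" else "non-stationary",
    n = n
  )
}

# t-statistic of rho in: diff(x) ~ 1 + lag(x)
df_tau <- function(x) {
  dy <- diff(x)
  yl <- x[-length(x)]
  fit <- stats::lm.fit(cbind(1, yl), dy)
  res <- fit$residuals
  dfree <- length(dy) - 2L
  s2 <- sum(res^2) / dfree
  xtx_inv <- chol2inv(chol(crossprod(cbind(1, yl))))
  fit$coefficients[2] / sqrt(s2 * xtx_inv[2, 2])
}
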