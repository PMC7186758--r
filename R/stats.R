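#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test with midranks for ties. For small samples
#' (`n_x + n_y <= 20`) without ties the exact null distribution of the
#' Mann-Whitney U statistic is used; otherwise a normal approximation with
#' tie-corrected variance and continuity correction. Two-sided by default.
#'
#' @param x,y numeric samples (each nonempty).
#' @param alternative "two.sided" (default), "less" or "greater".
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact branch; `NULL`
#'   chooses automatically.
#' @param correct apply the continuity correction in the normal branch.
#' @return an object of classes `rank_sum_test` and `htest` with elements
#'   `statistic` (z under the normal approximation, `NA` in the exact
#'   branch), `u` (Mann-Whitney U of `x`), `p.value`, `n`, `exact`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))$p.value  # 1/3 by exact enumeration
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "less", "greater"),
                          exact = NULL, correct = TRUE) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0 || anyNA(x) || anyNA(y)) {
    stopf("both samples must be nonempty and free of NA",
          class = "beesocial_stats_error")
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  u <- w - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- if (is.null(exact)) (n <= 20 && !ties) else isTRUE(exact)
  if (use_exact && ties) {
    stopf("exact rank-sum p-values are unavailable with ties",
          class = "beesocial_stats_error")
  }
  if (use_exact) {
    p_le <- stats::pwilcox(u, nx, ny)
    p_ge <- stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le,
                greater = p_ge)
    z <- NA_real_
  } else {
    mu <- nx * ny / 2
    tab <- table(r)
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      z <- 0
      p <- if (alternative == "two.sided") 1 else 1
    } else {
      d <- u - mu
      cc <- if (correct) {
        switch(alternative,
               two.sided = sign(d) * 0.5,
               less = -0.5,
               greater = 0.5)
      } else 0
      z <- (d - cc) / sqrt(sigma2)
      if (d == 0 && alternative == "two.sided") z <- 0
      p <- switch(alternative,
                  two.sided = 2 * stats::pnorm(-abs(z)),
                  less = stats::pnorm(z),
                  greater = stats::pnorm(z, lower.tail = FALSE))
      p <- min(1, p)
    }
  }
  structure(
    list(statistic = c(z = z), u = u, p.value = p,
         n = c(n_x = nx, n_y = ny), exact = use_exact,
         alternative = alternative,
         method = if (use_exact) "Wilcoxon rank-sum test (exact)"
                  else "Wilcoxon rank-sum test (normal approximation)",
         data.name = "x and y"),
    class = c("rank_sum_test", "htest")
  )
}

#' Rayleigh test of circular uniformity with optional weights
#'
#' Tests whether angles (e.g., body-axis orientations) are uniformly
#' distributed on the circle, optionally weighting each angle — typically by
#' the spike count observed in that frame, so the test asks whether spikes
#' are concentrated at particular orientations. With weights \eqn{w_i} and
#' angles \eqn{\theta_i}, the mean resultant length is
#' \eqn{\bar R = |\sum_i w_i e^{i\theta_i}| / \sum_i w_i}, the effective
#' sample size \eqn{n = \sum_i w_i}, \eqn{Z = n \bar R^2}, and
#' \eqn{p = e^{-Z}[1 + (2Z - Z^2)/(4n)]} clipped to [0, 1].
#'
#' @param angles_deg angles in degrees.
#' @param weights nonnegative weights, recycled to the length of
#'   `angles_deg`; their sum must be positive.
#' @return an object of classes `rayleigh_test` and `htest` with `statistic`
#'   (Z), `r_bar`, `n_eff`, `p.value`.
#' @export
rayleigh_test <- function(angles_deg, weights = NULL) {
  angles_deg <- as.numeric(angles_deg)
  keep <- !is.na(angles_deg)
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  weights <- rep_len(as.numeric(weights), length(angles_deg))
  angles_deg <- angles_deg[keep]; weights <- weights[keep]
  if (length(angles_deg) == 0 || anyNA(weights) || any(weights < 0)) {
    stopf("angles must be nonempty and weights nonnegative",
          class = "beesocial_stats_error")
  }
  n_eff <- sum(weights)
  if (n_eff <= 0) {
    stopf("all weights are zero: the Rayleigh test is undefined",
          class = "beesocial_stats_error")
  }
  th <- angles_deg * pi / 180
  c_sum <- sum(weights * cos(th))
  s_sum <- sum(weights * sin(th))
  r_bar <- sqrt(c_sum^2 + s_sum^2) / n_eff
  z <- n_eff * r_bar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n_eff))
  p <- min(1, max(0, p))
  structure(
    list(statistic = c(Z = z), r_bar = r_bar, n_eff = n_eff, p.value = p,
         method = "Rayleigh test of circular uniformity (weighted)",
         data.name = "angles_deg"),
    class = c("rayleigh_test", "htest")
  )
}

#' Rayleigh test on a binned angular rate profile
#'
#' The alternative weighting of the circular-uniformity question: instead of
#' weighting each frame's angle by its spike count, the binned mean-rate
#' vector from [angular_rate_profile()] is used, each bin midpoint weighted
#' by its mean rate (empty bins are skipped).
#'
#' @param profile output of [angular_rate_profile()].
#' @return a `rayleigh_test` result.
#' @export
rayleigh_profile_test <- function(profile) {
  ok <- !is.na(profile$mean_rate)
  rayleigh_test(profile$bin_mid_deg[ok], profile$mean_rate[ok])
}

#' Bonferroni-corrected per-comparison threshold
#'
#' @param alpha family-wise error level, in (0, 1).
#' @param m number of comparisons in the family (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 6)  # 0.00833..., the one-star level
#' @export
bonferroni_threshold <- function(alpha, m) {
  assert_scalar_num(alpha, "alpha", 1e-300, 1 - 1e-12)
  assert_scalar_num(m, "m", lower = 1)
  alpha / m
}

#' Pairwise spike-rate-variance comparisons between social states
#'
#' Runs a rank-sum test for every pair of states in the comparison family and
#' assigns star levels at Bonferroni-corrected thresholds: one star at
#' `0.05/m`, two at `0.01/m`, three at `0.005/m` (m = `n_comparisons`; with
#' the default 6-pair family these are the printed 0.0083 / 0.0017 / 0.00083
#' levels). The default family is the six pairs among the four non-alone
#' states (random, walking onset, passive contact, active contact) — an
#' alpha/6 correction implies a 6-pair family, which with five states can
#' only be the non-alone ones; `family = "all"` widens to all ten pairs and
#' corrects by 10.
#'
#' @param samples named list mapping state labels to numeric vectors of
#'   per-window spike-rate variances.
#' @param family "core" (four non-alone states, 6 pairs) or "all" (5 states,
#'   10 pairs).
#' @param alpha base family-wise level for the one-star threshold.
#' @return a data.frame with one row per pair in the family: `state1`,
#'   `state2`, `n1`, `n2`, `statistic`, `p`, `stars`, `tested`. Pairs whose
#'   states are missing or have fewer than two samples are reported untested
#'   (`tested = FALSE`, `p = NA`).
#' @export
pairwise_variance_comparisons <- function(samples,
                                          family = c("core", "all"),
                                          alpha = 0.05) {
  family <- match.arg(family)
  states <- if (family == "core") {
    setdiff(social_state_levels(), "alone")
  } else {
    social_state_levels()
  }
  pairs <- utils::combn(states, 2)
  m <- ncol(pairs)
  thresholds <- c(bonferroni_threshold(alpha, m),
                  bonferroni_threshold(alpha / 5, m),
                  bonferroni_threshold(alpha / 10, m))
  rows <- lapply(seq_len(m), function(i) {
    s1 <- pairs[1, i]; s2 <- pairs[2, i]
    a <- samples[[s1]]; b <- samples[[s2]]
    if (is.null(a) || is.null(b) || length(a) < 2 || length(b) < 2) {
      return(data.frame(state1 = s1, state2 = s2,
                        n1 = length(a %||% numeric(0)),
                        n2 = length(b %||% numeric(0)),
                        statistic = NA_real_, p = NA_real_,
                        stars = "", tested = FALSE,
                        stringsAsFactors = FALSE))
    }
    ts <- rank_sum_test(a, b)
    stars <- sum(ts$p.value <= thresholds)
    data.frame(state1 = s1, state2 = s2, n1 = length(a), n2 = length(b),
               statistic = unname(ts$statistic), p = ts$p.value,
               stars = strrep("*", stars), tested = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- thresholds
  attr(out, "family") <- family
  attr(out, "skipped") <- sum(!out$tested)
  out
}
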