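# Nonparametric rank statistics with effect sizes, implemented from first
# principles: Friedman (with Kendall's W), exact Wilcoxon signed-rank, exact
# Mann-Whitney U, Kruskal-Wallis (with eta squared), Dunn post-hoc tests,
# two-sample Kolmogorov-Smirnov, simple linear regression with an F-test, and
# Bonferroni adjustment. Exact p-values are computed by enumeration of the
# permutation distribution (via generating-function dynamic programming, which
# equals brute-force enumeration) within documented size limits; beyond them,
# normal/chi-square approximations with tie correction are used.

np_result <- function(test, statistic, df = NULL, p_value, effect_size = NULL,
                      method = "asymptotic", posthoc = NULL, extra = list()) {
  structure(c(list(test = test, statistic = statistic, df = df,
                   p_value = p_value, effect_size = effect_size,
                   method = method, posthoc = posthoc), extra),
            class = "np_test")
}

#' @export
print.np_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g", x$test, x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df = %s", paste(x$df, collapse = ",")))
  cat(sprintf(", p = %.4g (%s)", x$p_value, x$method))
  if (!is.null(x$effect_size))
    cat(sprintf(", effect size = %.4g", x$effect_size))
  cat("\n")
  if (!is.null(x$posthoc)) print(x$posthoc)
  invisible(x)
}

midranks <- function(x) rank(x, ties.method = "average")

two_sided_from_cdf <- function(p_le, p_ge) min(1, 2 * min(p_le, p_ge))

#' Kendall's coefficient of concordance from a Friedman chi-square
#'
#' `W = chi^2 / (N (k - 1))`, the untied-form effect size for a repeated
#' measures Friedman test over N subjects and k conditions.
#'
#' @param chisq Friedman chi-square statistic.
#' @param n number of subjects (N).
#' @param k number of conditions.
#' @return Kendall's W in `[0, 1]`.
#' @export
kendall_w <- function(chisq, n, k) {
  if (n < 2 || k < 2) stop("argument error: need n >= 2, k >= 2")
  chisq / (n * (k - 1))
}

#' Friedman rank test for repeated measures
#'
#' Values are mid-ranked within each subject; the chi-square statistic uses
#' the standard tie correction. Kendall's W is reported as
#' `chi^2 / (N (k - 1))` (untied form; set `tie_corrected_w = TRUE` for the
#' tie-corrected variant).
#'
#' @param x numeric matrix, N subjects (rows) x k conditions (columns), no
#'   missing cells.
#' @param tie_corrected_w report the tie-corrected Kendall's W instead.
#' @return an `np_test` with `statistic` (chi-square), `df = k - 1`,
#'   asymptotic `p_value` and `effect_size` (Kendall's W).
#' @export
friedman_rank_test <- function(x, tie_corrected_w = FALSE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("argument error: missing cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 3) stop("argument error: need N >= 2 subjects, k >= 3")
  R <- t(apply(x, 1, midranks))
  Rj <- colSums(R)
  Tt <- sum(apply(x, 1, function(row) {
    tt <- table(row); sum(tt^3 - tt)
  }))
  num <- 12 * sum((Rj - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - Tt / (k - 1)
  if (den <= 0) {
    chisq <- 0
  } else chisq <- num / den
  p <- pchisq(chisq, df = k - 1, lower.tail = FALSE)
  W <- kendall_w(chisq, n, k)
  if (tie_corrected_w) {
    W <- (12 * sum(Rj^2) - 3 * n^2 * k * (k + 1)^2) /
      (n^2 * k * (k^2 - 1) - n * Tt)
  }
  np_result("Friedman", chisq, df = k - 1, p_value = p, effect_size = W,
            method = "asymptotic", extra = list(n = n, k = k))
}

# distribution of the signed-rank statistic over all 2^n sign assignments,
# via the generating function prod_i (1 + t^(2 r_i)) on doubled mid-ranks.
signed_rank_distribution <- function(r2) {
  f <- numeric(sum(r2) + 1L)  # index s+1 holds count of doubled-sum s
  f[1] <- 1
  for (d in r2) {
    g <- f
    idx <- (d + 1L):length(f)
    g[idx] <- g[idx] + f[idx - d]
    f <- g
  }
  f / sum(f)
}

#' Wilcoxon signed-rank test (exact for n <= 25)
#'
#' Zero differences are dropped; tied magnitudes get mid-ranks. The statistic
#' is the sum of ranks of positive differences. The exact two-sided p-value
#' enumerates all `2^n` sign assignments (computed by dynamic programming,
#' identical to brute force); for n > `exact_max` a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param x,y paired samples, or differences in `x` with `y = NULL`.
#' @param exact_max largest n for exact enumeration.
#' @return an `np_test` with `statistic` (V), `p_value`, `method`, and the
#'   retained `n`.
#' @export
signed_rank_test <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) stop("degenerate error: all differences zero")
  r <- midranks(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    f <- signed_rank_distribution(r2)
    v2 <- round(2 * V)
    p_le <- sum(f[seq_len(v2 + 1L)])
    p_ge <- sum(f[(v2 + 1L):length(f)])
    p <- two_sided_from_cdf(p_le, p_ge)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tt <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "asymptotic"
  }
  np_result("Wilcoxon signed-rank", V, p_value = p, method = method,
            extra = list(n = n))
}

# distribution of the doubled rank sum of a size-m subset of doubled ranks r2
# over all choose(N, m) subsets; returns matrix-free vector of probabilities
rank_sum_distribution <- function(r2, m) {
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(m)])
  # f[c+1, s+1]: number of size-c subsets with doubled sum s
  f <- matrix(0, nrow = m + 1L, ncol = smax + 1L)
  f[1, 1] <- 1
  for (d in r2) {
    for (c in seq(min(m, 1e9), 1L)) {
      idx <- (d + 1L):(smax + 1L)
      f[c + 1L, idx] <- f[c + 1L, idx] + f[c, idx - d]
    }
  }
  f[m + 1L, ] / sum(f[m + 1L, ])
}

#' Mann-Whitney U test (exact for n1*n2 <= 400)
#'
#' Mid-ranks over the pooled sample; the statistic is
#' `U = R1 - n1 (n1 + 1) / 2` (the rank-sum form, matching the `W` reported
#' by common software). The exact two-sided p enumerates all
#' `choose(n1 + n2, n1)` group labelings (dynamic programming over the
#' observed, possibly tied, ranks); beyond the limit a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y independent samples.
#' @param exact_max largest `n1 * n2` for exact enumeration.
#' @return an `np_test` with `statistic` (U), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 400) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("argument error: empty group")
  r <- midranks(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  if (n1 * n2 <= exact_max) {
    r2 <- as.integer(round(2 * r))
    f <- rank_sum_distribution(r2, n1)
    s2 <- round(2 * R1)
    p_le <- sum(f[seq_len(s2 + 1L)])
    p_ge <- sum(f[(s2 + 1L):length(f)])
    p <- two_sided_from_cdf(p_le, p_ge)
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tt <- table(r)
    sigma2 <- n1 * n2 / 12 * (N + 1 - sum(tt^3 - tt) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "asymptotic"
  }
  np_result("Mann-Whitney U", U, p_value = p, method = method,
            extra = list(n1 = n1, n2 = n2))
}

#' Kruskal-Wallis rank test
#'
#' H with the standard tie correction, asymptotic chi-square p-value, and the
#' eta-squared effect size `(H - k + 1) / (n - k)`.
#'
#' @param groups list of numeric vectors (>= 2 groups, all non-empty, total
#'   n >= 3).
#' @return an `np_test` with `statistic` (H), `df = k - 1`, `p_value`,
#'   `effect_size` (eta squared).
#' @export
kruskal_wallis_test <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("argument error: need >= 2 groups")
  if (any(!lengths(groups))) stop("argument error: a group is empty")
  n <- sum(lengths(groups))
  if (n < 3) stop("argument error: total n < 3")
  g <- rep(seq_len(k), lengths(groups))
  r <- midranks(unlist(groups))
  Ri <- tapply(r, g, sum)
  ni <- lengths(groups)
  H <- 12 / (n * (n + 1)) * sum(Ri^2 / ni) - 3 * (n + 1)
  tt <- table(unlist(groups))
  corr <- 1 - sum(tt^3 - tt) / (n^3 - n)
  H <- if (corr > 0) H / corr else 0
  p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  eta2 <- (H - k + 1) / (n - k)
  np_result("Kruskal-Wallis", H, df = k - 1, p_value = p,
            effect_size = eta2, extra = list(n = n, k = k))
}

#' Dunn post-hoc pairwise comparisons
#'
#' Pairwise z statistics on pooled mean ranks with tie-corrected standard
#' errors, two-sided p-values, and Bonferroni adjustment over the
#' `k (k - 1) / 2` comparisons.
#'
#' @param groups named list of numeric vectors (>= 3 groups).
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return data frame with `pair`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  k <- length(groups)
  if (k < 3) stop("argument error: need >= 3 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  n <- sum(lengths(groups))
  g <- rep(names(groups), lengths(groups))
  r <- midranks(unlist(groups))
  mr <- tapply(r, g, mean)[names(groups)]
  ni <- setNames(lengths(groups), names(groups))
  tt <- table(unlist(groups))
  tiecor <- sum(tt^3 - tt) / (12 * (n - 1))
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- names(groups)[i]; b <- names(groups)[j]
    se <- sqrt((n * (n + 1) / 12 - tiecor) * (1 / ni[[a]] + 1 / ni[[b]]))
    z <- (mr[[a]] - mr[[b]]) / se
    out[[length(out) + 1L]] <- data.frame(
      pair = paste(a, b, sep = "-"), z = z,
      p_raw = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  m <- k * (k - 1) / 2
  tab$p_adjusted <- if (adjust == "bonferroni")
    bonferroni_adjust(tab$p_raw, m) else tab$p_raw
  tab
}

# number of monotone lattice paths staying strictly inside |i/m - j/n| < d,
# checked only at pooled positions where the next value differs (tie blocks
# are traversed freely); denominator choose(m+n, m).
ks_exact_p <- function(z_pooled, m, n, d) {
  N <- m + n
  zs <- sort(z_pooled)
  # is position i+j (1-based cumulative count) a checkpoint?
  checkpoint <- c(zs[-N] != zs[-1], TRUE)
  prev <- numeric(n + 1L)
  prev[1] <- 1
  for (i in 0:m) {
    cur <- numeric(n + 1L)
    for (j in 0:n) {
      tot <- i + j
      ok <- tot == 0 || tot == N || !checkpoint[tot] ||
        abs(i / m - j / n) < d - 1e-12
      if (!ok) { cur[j + 1L] <- 0; next }
      acc <- if (i > 0) prev[j + 1L] else 0
      if (j > 0) acc <- acc + cur[j]
      if (tot == 0) acc <- 1
      cur[j + 1L] <- acc
    }
    prev <- cur
  }
  1 - prev[n + 1L] / choose(N, m)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |F1 - F2|` over the pooled values. The p-value is exact (lattice
#' path counting over all group labelings, valid with ties) for
#' `n1 * n2 <= exact_max`, otherwise the asymptotic Kolmogorov distribution.
#'
#' @param x,y independent samples.
#' @param exact_max largest `n1 * n2` for the exact computation.
#' @return an `np_test` with `statistic` (D), `p_value`, `method`.
#' @export
ks2_test <- function(x, y, exact_max = 400) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("argument error: empty sample")
  pooled <- c(x, y)
  zs <- sort(unique(pooled))
  D <- max(abs(ecdf(x)(zs) - ecdf(y)(zs)))
  if (n1 * n2 <= exact_max) {
    p <- ks_exact_p(pooled, n1, n2, D)
    method <- "exact"
  } else {
    ne <- n1 * n2 / (n1 + n2)
    lam <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
    kk <- 1:100
    p <- min(1, max(0, 2 * sum((-1)^(kk - 1) * exp(-2 * kk^2 * lam^2))))
    method <- "asymptotic"
  }
  np_result("Kolmogorov-Smirnov", D, p_value = p, method = method,
            extra = list(n1 = n1, n2 = n2))
}

#' Simple linear regression with an F-test of overall significance
#'
#' Ordinary least squares for `y = b0 + b1 x + e` in closed form;
#' `F = MSR / MSE` on `(1, n - 2)` degrees of freedom. An exact fit reports
#' `F = Inf` with `p = 0`.
#'
#' @param x,y numeric vectors, `n >= 3`; `x` must not be constant.
#' @return list with `beta0`, `beta1`, `f_statistic`, `df`, `p_value`,
#'   `r_squared`, `n`.
#' @export
linear_regression_f <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("argument error: need n >= 3")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("singular-design error: constant x")
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b0 <- mean(y) - b1 * mean(x)
  fit <- b0 + b1 * x
  ssr <- sum((fit - mean(y))^2)
  sse <- sum((y - fit)^2)
  r2 <- if (ssr + sse == 0) 1 else ssr / (ssr + sse)
  if (sse <= 1e-12 * max(ssr, 1)) {
    f <- Inf; p <- 0
  } else {
    f <- ssr / (sse / (n - 2))
    p <- pf(f, 1, n - 2, lower.tail = FALSE)
  }
  list(beta0 = b0, beta1 = b1, f_statistic = f, df = c(1, n - 2),
       p_value = p, r_squared = r2, n = n)
}

#' Pairwise Wilcoxon signed-rank tests across conditions
#'
#' Post-hoc companion to [friedman_rank_test()]: every pair of columns is
#' compared with an exact signed-rank test and Bonferroni-adjusted over all
#' `k (k - 1) / 2` pairs.
#'
#' @param x numeric matrix, subjects x conditions (named columns).
#' @return data frame with `pair`, `statistic` (V), `p_raw`, `p_adjusted`.
#' @export
pairwise_signed_rank <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x)
  if (k < 2) stop("argument error: need >= 2 conditions")
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("c", seq_len(k))
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    w <- signed_rank_test(x[, i], x[, j])
    out[[length(out) + 1L]] <- data.frame(
      pair = paste(nms[i], nms[j], sep = "-"),
      statistic = w$statistic, p_raw = w$p_value, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab$p_adjusted <- bonferroni_adjust(tab$p_raw, k * (k - 1) / 2)
  tab
}

#' Bonferroni adjustment
#'
#' `min(1, m p)` elementwise.
#'
#' @param p p-values in `[0, 1]`.
#' @param m number of comparisons (>= `length(p)`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("argument error: p outside [0, 1]")
  if (m < length(p)) stop("argument error: m < number of p-values")
  pmin(1, m * p)
}
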