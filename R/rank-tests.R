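# Rank-based two-group and paired tests, implemented from the exact
# combinatorial null distributions (dynamic programming over rank sums)
# with a tie/asymptotic fallback. Kept independent of stats::wilcox.test so
# the two routes can be cross-checked in the test suite.

# number of ways to pick `n` of the ranks 1..(n+m) with rank-sum offset u,
# i.e. the Mann-Whitney U null distribution: counts[u+1], u = 0..n*m
.mw_counts <- function(n, m) {
  # subset-sum DP: ways[j+1, s+1] = number of size-j subsets of ranks seen
  # so far with rank-sum s; U = sum - n(n+1)/2
  N <- n + m
  smax <- sum((m + 1):N)                          # largest possible rank sum
  ways <- matrix(0, nrow = n + 1, ncol = smax + 1)
  ways[1, 1] <- 1
  for (k in seq_len(N)) {
    for (j in min(k, n):1) {
      ways[j + 1, (k + 1):(smax + 1)] <-
        ways[j + 1, (k + 1):(smax + 1)] + ways[j, 1:(smax + 1 - k)]
    }
  }
  smin <- n * (n + 1) / 2
  ways[n + 1, (smin:smax) + 1]                    # index u+1 <-> U = u
}

# signed-rank V null distribution over ranks 1..n: counts[v+1], v=0..n(n+1)/2
.sr_counts <- function(n) {
  vmax <- n * (n + 1) / 2
  cnt <- numeric(vmax + 1)
  cnt[1] <- 1
  for (r in seq_len(n)) {
    shifted <- c(numeric(r), cnt[seq_len(vmax + 1 - r)])
    cnt <- cnt + shifted
  }
  cnt
}

#' Two-sample Mann-Whitney (rank-sum) test
#'
#' Exact null distribution (dynamic programming) when both groups have at
#' most `exact_max` observations and the pooled values contain no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction. The reported statistic is U for the first group.
#'
#' @param x,y numeric vectors (each with at least 2 values).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param exact_max maximum group size for the exact branch (default 50).
#' @return list(statistic = U, p.value, method).
#' @export
mann_whitney_test <- function(x, y,
                              alternative = c("two.sided", "greater", "less"),
                              exact_max = 50) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n <- length(x); m <- length(y)
  if (n < 2 || m < 2) stop("need at least 2 values per group")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n <= exact_max && m <= exact_max) {
    cnt <- .mw_counts(n, m)
    total <- sum(cnt)
    cdf_le <- cumsum(cnt) / total                   # P(U <= u)
    p_le <- function(u) if (u < 0) 0 else cdf_le[min(u, n * m) + 1]
    p_ge <- function(u) 1 - p_le(u - 1)
    p <- switch(alternative,
                greater = p_ge(U),
                less = p_le(U),
                two.sided = {
                  pp <- if (U > n * m / 2) p_ge(U) else p_le(U)
                  min(2 * pp, 1)
                })
    method <- "exact"
  } else {
    mu <- n * m / 2
    nt <- n + m
    tie_tab <- table(r)
    sigma2 <- (n * m / 12) * ((nt + 1) - sum(tie_tab^3 - tie_tab) /
                                (nt * (nt - 1)))
    sigma <- sqrt(sigma2)
    cc <- switch(alternative, two.sided = sign(U - mu) * 0.5,
                 greater = 0.5, less = -0.5)
    zstat <- (U - mu - cc) / sigma
    p <- switch(alternative,
                greater = pnorm(zstat, lower.tail = FALSE),
                less = pnorm(zstat),
                two.sided = 2 * min(pnorm(zstat),
                                    pnorm(zstat, lower.tail = FALSE)))
    p <- min(p, 1)
    method <- "normal approximation"
  }
  if (length(unique(c(x, y))) == 1) {
    warning("all values tied; p = 1")
    p <- 1
  }
  list(statistic = U, p.value = p, method = method)
}

#' One-sample / paired Wilcoxon signed-rank test
#'
#' Tests symmetry of `d` about 0 (for paired data pass `d = b - a`). Zero
#' differences are dropped (standard convention). Exact DP distribution
#' when `n <= exact_max` and no ties among |d|; otherwise normal
#' approximation with tie and continuity corrections. If every difference
#' is zero the test is undefined and p = 1 is returned with a warning.
#'
#' @param d numeric vector of differences.
#' @param alternative `"two.sided"`, `"greater"` (shifted above 0) or
#'   `"less"`.
#' @param exact_max maximum n for the exact branch (default 50).
#' @return list(statistic = V, p.value, n_used, method).
#' @export
signed_rank_test <- function(d, alternative = c("two.sided", "greater", "less"),
                             exact_max = 50) {
  alternative <- match.arg(alternative)
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences zero; signed-rank test undefined, p = 1")
    return(list(statistic = NA_real_, p.value = 1, n_used = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= exact_max) {
    cnt <- .sr_counts(n)
    total <- 2^n
    vmax <- n * (n + 1) / 2
    cdf_le <- cumsum(cnt) / total
    p_le <- function(v) if (v < 0) 0 else cdf_le[min(v, vmax) + 1]
    p_ge <- function(v) 1 - p_le(v - 1)
    p <- switch(alternative,
                greater = p_ge(V),
                less = p_le(V),
                two.sided = {
                  pp <- if (V > vmax / 2) p_ge(V) else p_le(V)
                  min(2 * pp, 1)
                })
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    sigma <- sqrt(sigma2)
    cc <- switch(alternative, two.sided = sign(V - mu) * 0.5,
                 greater = 0.5, less = -0.5)
    zstat <- (V - mu - cc) / sigma
    p <- switch(alternative,
                greater = pnorm(zstat, lower.tail = FALSE),
                less = pnorm(zstat),
                two.sided = 2 * min(pnorm(zstat),
                                    pnorm(zstat, lower.tail = FALSE)))
    p <- min(p, 1)
    method <- "normal approximation"
  }
  list(statistic = V, p.value = p, n_used = n, method = method)
}
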