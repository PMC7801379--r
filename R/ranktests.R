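# Rank statistics used throughout the package: the paired Wilcoxon
# signed-rank test (the paired analogue of the Mann-Whitney test named in the
# analysis), the two-sample Mann-Whitney rank-sum test, and step-down
# Holm-Bonferroni adjustment.
#
# Exact null distributions are computed by dynamic programming over doubled
# midranks (so tied absolute differences stay exact); two-sided p-values are
# 2 * min(P(W <= w), P(W >= w)) capped at 1. Beyond the exact-size limit a
# normal approximation with tie and continuity correction is used.

# subset-sum distribution of doubled ranks: returns counts f[s+1] = number of
# subsets with sum s (total 2^n subsets)
.signed_rank_counts <- function(r2) {
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in r2) {
    idx <- (total + 1L):(r + 1L)
    f[idx] <- f[idx] + f[idx - r]
  }
  f
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on a vector of paired differences. Zero differences are
#' dropped (the Wilcoxon convention). With `n <= exact_max` remaining pairs
#' the exact null distribution of the rank sum of positive differences is
#' enumerated by dynamic programming over doubled midranks; otherwise a
#' normal approximation with tie and continuity correction is used.
#'
#' @param d numeric vector of paired differences (`b - a`).
#' @param exact_max largest `n` for which the exact distribution is used.
#' @return list with `n` (nonzero pairs), `statistic` (rank sum of positive
#'   differences, midranks), `p` (two-sided; `NA` when `n == 0`), and
#'   `method` (`"exact"`/`"normal"`/`"none"`).
#' @export
signed_rank_test <- function(d, exact_max = 25L) {
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) return(list(n = 0L, statistic = NA_real_, p = NA_real_, method = "none"))
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * rk))
    f <- .signed_rank_counts(r2)
    w2 <- as.integer(round(2 * W))
    tot <- 2^n
    p_le <- sum(f[seq_len(w2 + 1L)]) / tot
    p_ge <- sum(f[(w2 + 1L):length(f)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    list(n = n, statistic = W, p = p, method = "exact")
  } else {
    mu <- n * (n + 1) / 4
    ties <- rle(sort(rk))$lengths
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(W - mu) - 0.5) / sqrt(sig2)
    z <- max(z, 0)
    p <- min(1, 2 * pnorm(-z))
    list(n = n, statistic = W, p = p, method = "normal")
  }
}

#' Two-sample Mann-Whitney rank-sum test
#'
#' Two-sided comparison of two independent value sets, used for SE-vs-TE
#' response comparisons. Exact by dynamic programming over doubled midranks
#' when the combined sample size is at most `exact_max`; normal approximation
#' with tie and continuity correction otherwise.
#'
#' @param a,b numeric vectors (non-empty).
#' @param exact_max largest combined `n` for the exact distribution.
#' @return list with `p`, `statistic` (rank sum of `a`, midranks),
#'   `median_a`, `median_b`, `method`.
#' @export
rank_sum_test <- function(a, b, exact_max = 20L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("invalid input: both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  rk <- rank(c(a, b))
  W <- sum(rk[seq_len(n1)])
  if (N <= exact_max) {
    r2 <- as.integer(round(2 * rk))
    tot_sum <- sum(r2)
    # g[k+1, s+1] = number of size-k subsets of r2 with doubled-rank sum s
    g <- matrix(0, nrow = n1 + 1L, ncol = tot_sum + 1L)
    g[1L, 1L] <- 1
    for (r in r2) {
      for (k in n1:1L) {
        idx <- (tot_sum + 1L):(r + 1L)
        g[k + 1L, idx] <- g[k + 1L, idx] + g[k, idx - r]
      }
    }
    counts <- g[n1 + 1L, ]
    tot <- sum(counts)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(counts[seq_len(w2 + 1L)]) / tot
    p_ge <- sum(counts[(w2 + 1L):length(counts)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * (N + 1) / 2
    ties <- rle(sort(rk))$lengths
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- max((abs(W - mu) - 0.5) / sqrt(sig2), 0)
    p <- min(1, 2 * pnorm(-z))
    method <- "normal"
  }
  list(p = p, statistic = W, median_a = median(a), median_b = median(b),
       method = method)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values in the input order: sorted ascending,
#'   `adj[i] = max_{j <= i} (m - j + 1) * p[j]`, capped at 1.
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02 0.04
#' @export
holm_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("invalid input: p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}
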