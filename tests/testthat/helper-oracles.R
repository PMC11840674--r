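# Independent enumeration oracles used by both the unit and the
# acceptance suites. These re-derive the exact null distributions from
# first principles and never call the code paths they check.

# full Mann-Whitney U null distribution via the memoised counting
# recursion c(m, n, u) = c(m-1, n, u-n) + c(m, n-1, u)
.uDistribution <- function(m, n) {
  memo <- new.env()
  cnt <- function(m, n, u) {
    if (u < 0 || u > m * n) return(0)
    if (m == 0 || n == 0) return(as.numeric(u == 0))
    key <- paste(m, n, u)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- cnt(m - 1, n, u - n) + cnt(m, n - 1, u)
    memo[[key]] <- v
    v
  }
  counts <- vapply(0:(m * n), function(u) cnt(m, n, u), numeric(1))
  counts / sum(counts)
}

.uTwoSidedP <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  d <- .uDistribution(m, n)
  mid <- m * n / 2
  p <- if (u > mid) sum(d[(u + 1):(m * n + 1)]) else sum(d[1:(u + 1)])
  min(1, 2 * p)
}

# signed-rank two-sided p by enumerating all 2^n sign patterns
.signedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- as.vector(signs %*% r)
  mid <- n * (n + 1) / 4
  p <- if (v > mid) mean(w >= v) else mean(w <= v)
  min(1, 2 * p)
}

# Fisher two-sided p by hypergeometric minimum-likelihood summation
.fisherP <- function(tab) {
  x <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  d <- dhyper(lo:hi, m, n, k)
  sum(d[d <= dhyper(x, m, n, k) * (1 + 1e-7)])
}

# exact two-sided binomial p by explicit log-space pmf accumulation,
# independent of stats::dbinom vector enumeration in the implementation
.binomMinlikeP <- function(k, n, p0) {
  logpmf <- vapply(0:n, function(j)
    lchoose(n, j) + j * log(p0) + (n - j) * log1p(-p0), numeric(1))
  pmf <- exp(logpmf)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

# textbook BH step-up: adjusted values by the running minimum from the
# largest p, and the rejection set by exhaustive threshold search
.bhOracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    q[o[i]] <- running
  }
  kmax <- 0
  for (k in seq_len(m))
    if (p[o[k]] <= k * alpha / m) kmax <- k
  reject <- rep(FALSE, m)
  if (kmax > 0) reject[o[seq_len(kmax)]] <- TRUE
  list(adjusted = q, reject = reject)
}
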