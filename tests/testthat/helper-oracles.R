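# Independent oracles kept deliberately separate from the package internals.

# type-7 quantile by explicit sorted interpolation
oracle_quantile7 <- function(x, p) {
  x <- sort(unname(x[!is.na(x)]))
  n <- length(x)
  if (n == 1L) return(rep(x, length(p)))
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- pmin(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# D metric from first principles
oracle_distance <- function(sens_values, res_values) {
  sq <- oracle_quantile7(sens_values, c(0.5, 0.75))
  rq <- oracle_quantile7(res_values, c(0.5, 0.75))
  (sq[1] - rq[1]) + (sq[2] - rq[2])
}

# Welch two-sided p from the textbook formula
oracle_welch_p <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

# BH step-up by brute force over the sort order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (i in rev(seq_len(m))) {
    running_min <- min(running_min, p[o[i]] * m / i)
    adj[o[i]] <- running_min
  }
  pmin(adj, 1)
}

# upper-tail hypergeometric P(X >= a) by exhaustive enumeration
oracle_hyper_upper <- function(a, c_in_set, d_total, b_draws) {
  hi <- min(b_draws, c_in_set)
  if (a > hi) return(0)
  lo <- max(a, b_draws - (d_total - c_in_set), 0)
  ks <- lo:hi
  sum(choose(c_in_set, ks) * choose(d_total - c_in_set, b_draws - ks)) /
    choose(d_total, b_draws)
}

# Spearman rho from explicit ranks + Pearson covariance formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Smyth-style moment estimation of (d0, s0^2), written independently:
# operates on the vector of variances and (constant) dfs directly
oracle_fdist_moments <- function(s2, df1) {
  z <- log(s2)
  e <- z - digamma(df1 / 2) + log(df1 / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df1 / 2)
  if (evar > 0) {
    # invert trigamma by bisection (independent of the package's Newton)
    f <- function(y) trigamma(y) - evar
    lo <- 1e-8; hi <- 1e8
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    d0 <- 2 * sqrt(lo * hi)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0)
}
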