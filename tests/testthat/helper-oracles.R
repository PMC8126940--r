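# Independent brute-force oracles, implemented by different routes than the
# package functions they check.

# Pearson chi-square by explicit margin arithmetic
oracle_chisq <- function(m) {
  n <- sum(m)
  stat <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    e <- sum(m[i, ]) * sum(m[, j]) / n
    stat <- stat + (m[i, j] - e)^2 / e
  }
  list(statistic = stat, df = (nrow(m) - 1) * (ncol(m) - 1))
}

# One-way ANOVA by explicit sums of squares, Tukey p by ptukey
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  lv <- levels(groups)
  ssb <- 0; ssw <- 0
  for (g in lv) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  df1 <- length(lv) - 1
  df2 <- length(values) - length(lv)
  f <- (ssb / df1) / (ssw / df2)
  mse <- ssw / df2
  pairs <- utils::combn(lv, 2)
  p_adj <- apply(pairs, 2, function(pr) {
    n1 <- sum(groups == pr[1]); n2 <- sum(groups == pr[2])
    d <- abs(mean(values[groups == pr[1]]) - mean(values[groups == pr[2]]))
    se <- sqrt(mse / 2 * (1 / n1 + 1 / n2))
    stats::ptukey(d / se, nmeans = length(lv), df = df2, lower.tail = FALSE)
  })
  list(f = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       p_adj = p_adj,
       comparison = apply(pairs, 2, function(pr) paste(pr[2], pr[1], sep = "-")))
}

# Cronbach's alpha via the covariance-matrix route:
# alpha = k/(k-1) * (1 - tr(C) / sum(C))
oracle_alpha <- function(x) {
  C <- stats::cov(x)
  k <- ncol(x)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# Two-way ANOVA mean squares for ICC(A,1) via explicit loops
oracle_icc <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ssr <- 0; ssc <- 0; sst <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - grand)^2
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (x[i, j] - grand)^2
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Discounted year-equivalents by explicit year-by-year loop
oracle_discounted <- function(T_years, r) {
  if (r == 0) return(T_years)
  acc <- 0
  t <- 1
  while (t <= floor(T_years)) {
    acc <- acc + (1 + r)^(-t)
    t <- t + 1
  }
  frac <- T_years - floor(T_years)
  if (frac > 0) acc <- acc + frac * (1 + r)^(-ceiling(T_years))
  acc
}

# Closed-form moments of Normal(mu, sd) truncated below at a
trunc_norm_moments <- function(mu, sd, a) {
  z <- (a - mu) / sd
  lam <- stats::dnorm(z) / (1 - stats::pnorm(z))
  m <- mu + sd * lam
  v <- sd^2 * (1 + z * lam - lam^2)
  list(mean = m, var = v)
}

# A small EPQ sheet realizing given subscale scores under the default key
make_sheet <- function(e = 0, n = 0, p = 0, l = 0, key = epq_default_key()) {
  ans <- integer(48)
  target <- c(E = e, N = n, P = p, L = l)
  for (sub in names(target)) {
    idx <- which(key$subscale == sub)
    hit <- idx[seq_len(target[[sub]])]
    ans[hit] <- key$keyed_answer[hit]
    rest <- setdiff(idx, hit)
    ans[rest] <- 1L - key$keyed_answer[rest]
  }
  ans
}
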