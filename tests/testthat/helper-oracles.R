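# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: normal equations instead of QR, explicit pmf sums
# instead of pbinom tails, full relabeling enumeration for PERMANOVA.

# OLS via normal equations: solve(X'X) X'y, textbook standard errors
oracle_ols <- function(X, y) {
  X <- as.matrix(X); y <- as.numeric(y)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- unname(sqrt(diag(xtx_inv) * s2))
  tstat <- as.numeric(beta) / se
  list(coef = as.numeric(beta), se = se,
       p = unname(2 * pt(-abs(tstat), df)), rss = sum(res^2), df = df)
}

# BH step-up from the definition: q_i = min over j with p_(j) >= p_(i)
# of m * p_(j) / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  adj <- m * p[ord] / seq_len(m)
  # step-up: running minimum from the largest p downward
  for (i in m:1) adj[i] <- min(adj[i:m])
  q[ord] <- pmin(adj, 1)
  q
}

# Bray-Curtis of two vectors, from the definition
oracle_bray <- function(x, y) 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))

# one-factor pseudo-F of a distance matrix from within-group sums
# (Anderson's formulation via SS_total - SS_within, no Gower matrix)
oracle_pseudo_f <- function(d, labels) {
  n <- nrow(d)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    sub <- d[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  a <- length(unique(labels))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# exact two-group PERMANOVA p by enumerating every relabeling
oracle_permanova_exhaustive <- function(d, labels) {
  n <- nrow(d)
  lev <- sort(unique(labels))
  n1 <- sum(labels == lev[1])
  f_obs <- oracle_pseudo_f(d, labels)
  combos <- combn(n, n1)
  fs <- apply(combos, 2, function(idx) {
    lab <- rep(lev[2], n); lab[idx] <- lev[1]
    oracle_pseudo_f(d, lab)
  })
  list(f = f_obs, p = sum(fs >= f_obs - 1e-12) / length(fs), n_relabel = ncol(combos))
}

# exact binomial upper tail by summing the pmf term by term
oracle_binom_tail <- function(k, R, p) {
  if (k > R) return(0)
  sum(vapply(k:R, function(x) choose(R, x) * p^x * (1 - p)^(R - x), numeric(1)))
}

# count threshold by scanning the summed-pmf tail
oracle_count_threshold <- function(R, alpha0, m, alpha = 0.05) {
  if (alpha / m >= 1) return(0L)
  for (k in 0:R) {
    if (oracle_binom_tail(k, R, alpha0) <= alpha / m) return(as.integer(k - 1))
  }
  stop("no threshold")
}
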