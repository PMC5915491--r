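# Independent oracles: every implementation below deliberately avoids the
# package's own code paths (no shared solvers, sum-formula statistics,
# exhaustive enumeration) so agreement is evidence, not tautology.

# Laplacian-score fixed point: x <- balance * S %*% x + (1 - balance) * d,
# whose limit is the global-similarity column (1-b)(I - b S)^{-1} d
fixed_point_oracle <- function(s_bar, d, balance, tol = 1e-12,
                               max_iter = 100000L) {
  x <- (1 - balance) * d
  for (i in seq_len(max_iter)) {
    x_new <- balance * as.vector(s_bar %*% x) + (1 - balance) * d
    if (sum(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  stop("oracle fixed point did not converge")
}

# direct linear-solve stationary distribution of a restart walk
rwr_solve_oracle <- function(s_bar, seed, restart) {
  n <- nrow(s_bar)
  restart * solve(diag(n) - (1 - restart) * s_bar, seed)
}

# textbook sum-formula Pearson correlation
pearson_sum_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# exhaustive pairwise U-statistic AUC: P(pos > neg) + 0.5 P(tie)
auc_u_oracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

# precision/recall by explicit confusion-matrix enumeration at each threshold
pr_enum_oracle <- function(pos, neg) {
  ts <- sort(unique(c(pos, neg)), decreasing = TRUE)
  do.call(rbind, lapply(ts, function(t) {
    tp <- sum(pos >= t); fp <- sum(neg >= t)
    data.frame(threshold = t, recall = tp / length(pos),
               precision = tp / (tp + fp))
  }))
}

# random symmetric non-negative similarity matrix with unit diagonal
rand_sim <- function(n, labels = sprintf("e%02d", seq_len(n))) {
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(labels, labels)
  m
}
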