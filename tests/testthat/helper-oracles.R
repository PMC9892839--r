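# Independent brute-force oracles shared by the statistics and calibration
# tests. Each recomputes its quantity from first principles, never through
# the package's code path.

pearson_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a, r1, r2, c1)
  pobs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

mw_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  u_all <- apply(combs, 2, function(i) sum(seq_len(n)[i]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  list(u = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

signed_rank_oracle <- function(d) {
  # one-sided P(W+ >= observed) by enumeration of all sign assignments
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  w_all <- signs %*% r
  mean(w_all >= w_obs - 1e-9)
}
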