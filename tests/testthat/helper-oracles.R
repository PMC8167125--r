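# Independent brute-force oracles used to pin expected values.

# Exact two-sided Mann-Whitney p by enumeration of all rank assignments.
brute_mwu <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(na + nb, na)
  u_all <- apply(splits, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of sign patterns.
brute_wsr <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  list(W = w_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Kruskal-Wallis H by direct evaluation of the rank formula (tie-corrected).
brute_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Monte-Carlo permutation p-value for Kruskal-Wallis.
perm_kw_p <- function(groups, n_perm = 10000, seed = 1) {
  x <- unlist(groups)
  sizes <- lengths(groups)
  h_obs <- brute_kw_h(groups)
  set.seed(seed)
  hits <- 0
  for (i in seq_len(n_perm)) {
    xp <- sample(x)
    gp <- split(xp, rep(seq_along(sizes), sizes))
    if (brute_kw_h(gp) >= h_obs - 1e-12) hits <- hits + 1
  }
  hits / n_perm
}

# Brute-force central moments.
brute_skew <- function(v) {
  m <- mean(v)
  mean((v - m)^3) / mean((v - m)^2)^1.5
}
brute_kurt <- function(v) {
  m <- mean(v)
  mean((v - m)^4) / mean((v - m)^2)^2 - 3
}
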