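# Independent oracles used to freeze expected values. These deliberately use
# naive/direct computations (full enumeration, O(n^2) convolution) rather
# than the package's own code paths.

# direct discrete convolution, truncated to length(x)
conv_oracle <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    jmax <- min(i, length(k))
    out[i] <- sum(x[i - seq_len(jmax) + 1] * k[seq_len(jmax)])
  }
  out
}

# two-sided Mann-Whitney p by full enumeration of group assignments
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combs <- utils::combn(n, n1)
  cnt <- 0
  for (j in seq_len(ncol(combs))) {
    u <- sum(r[combs[, j]]) - n1 * (n1 + 1) / 2
    if (abs(u - mu) >= abs(u_obs - mu) - 1e-9) cnt <- cnt + 1
  }
  cnt / ncol(combs)
}

# all permutations of 1..k as rows
perms_oracle <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perms_oracle(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

# tie-corrected Friedman statistic computed directly from a block matrix
friedman_stat_oracle <- function(mat) {
  b <- nrow(mat); k <- ncol(mat)
  R <- t(apply(mat, 1, rank))
  A <- sum(R^2)
  C <- b * k * (k + 1)^2 / 4
  if (A - C <= 1e-12) return(0)
  (k - 1) * sum((colSums(R) - b * (k + 1) / 2)^2) / (A - C)
}

# exact Friedman p by brute-force enumeration of all within-block
# permutations (feasible for b <= 4, k = 3)
friedman_enum_oracle <- function(mat) {
  b <- nrow(mat); k <- ncol(mat)
  P <- perms_oracle(k)
  obs <- friedman_stat_oracle(mat)
  idx <- rep(list(seq_len(nrow(P))), b)
  grid <- as.matrix(expand.grid(idx))
  cnt <- 0
  for (g in seq_len(nrow(grid))) {
    m <- mat
    for (i in seq_len(b)) m[i, ] <- mat[i, P[grid[g, i], ]]
    if (friedman_stat_oracle(m) >= obs - 1e-9) cnt <- cnt + 1
  }
  cnt / nrow(grid)
}

# permutation p-value for the ATS habituation test: shuffle time points
# within each fish
ats_perm_oracle <- function(x, B = 2000, seed = 1) {
  set.seed(seed)
  obs <- test_habituation(x)$statistic
  cnt <- 0
  for (b in seq_len(B)) {
    xp <- t(apply(x, 1, sample))
    if (test_habituation(xp)$statistic >= obs - 1e-12) cnt <- cnt + 1
  }
  (cnt + 1) / (B + 1)
}

# small cohort configuration for fast tests
small_config <- function(...) {
  cohort_config(n_fish = 4, rois_per_fish = 150,
                class_mix = c(dim = 0.05, checker = 0.25, both = 0.10,
                              none = 0.60), ...)
}
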