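# Independent brute-force oracles. These re-derive the expected results by
# enumeration or exhaustive search and never call the package's own code.

# Exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1) rank
# assignments of the first group (tie-free data only).
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- apply(sets, 2L, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign
# assignments of the ranks of |d| (nonzero tie-free differences only).
sr_enum_oracle <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  list(w = w_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# Component-scaled closeness from a Floyd-Warshall all-pairs distance
# matrix with edge lengths 1/weight.
closeness_fw_oracle <- function(weights) {
  n <- nrow(weights)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && weights[i, j] > 0) d[i, j] <- 1 / weights[i, j]
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    reach <- is.finite(dv)
    m <- sum(reach) + 1
    if (m <= 1) return(0)
    ((m - 1) / sum(dv[reach])) * ((m - 1) / (n - 1))
  }, 0)
}

# Midrank (Mann-Whitney) AUC of scores for binary labels, positive = "tumor".
auc_rank_oracle <- function(scores, labels) {
  pos <- labels == "tumor"
  r <- rank(scores)
  (mean(r[pos]) - (sum(pos) + 1) / 2) / sum(!pos)
}

# Random symmetric weight matrix in [0,1] with zero diagonal and a given
# edge density; used as a generic small-graph generator.
random_weight_matrix <- function(n, density = 0.5) {
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- sample(up, round(density * length(up)))
  w[on] <- stats::runif(length(on), 0.05, 1)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  w
}
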