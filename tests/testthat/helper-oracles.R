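# Independent oracles used to validate the implementation. These recompute
# quantities from first principles (direct summation, exhaustive
# enumeration, normal equations) and are deliberately written without
# reference to the package's own code paths.

# Direct-summation signed modularity: brute-force evaluation of
# Q* = Q+ - (v-/(v+ + v-)) Q- over ordered node pairs. The weight diagonal
# is zero and the null (strength-product) term runs over all pairs, the
# convention under which the single-community partition scores exactly 0.
qstar_oracle <- function(W, labels) {
  diag(W) <- 0
  Wp <- pmax(W, 0)
  Wn <- pmax(-W, 0)
  vp <- sum(Wp)
  vn <- sum(Wn)
  if (vp + vn == 0) return(0)
  part <- function(A, v) {
    if (v <= 0) return(0)
    s <- rowSums(A)
    q <- 0
    n <- nrow(A)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (labels[i] == labels[j]) {
          q <- q + A[i, j] - s[i] * s[j] / v
        }
      }
    }
    q / v
  }
  part(Wp, vp) - (vn / (vp + vn)) * part(Wn, vn)
}

# Faster direct evaluation used inside the exhaustive-enumeration loop
# (same formula, matrix form).
qstar_oracle_fast <- function(Wp, Wn, sp, sn, vp, vn, labels) {
  D <- outer(labels, labels, "==")
  qp <- if (vp > 0) (sum(Wp[D]) - sum((outer(sp, sp) / vp)[D])) / vp else 0
  qn <- if (vn > 0) (sum(Wn[D]) - sum((outer(sn, sn) / vn)[D])) / vn else 0
  if (vp + vn == 0) return(0)
  qp - (vn / (vp + vn)) * qn
}

# All set partitions of n elements as restricted growth strings.
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- labels
      return()
    }
    for (c in seq_len(k + 1)) rec(c(labels, c), max(k, c))
  }
  rec(integer(0), 0)
  out
}

# Exhaustive-enumeration two-sided rank-sum p-value (no ties), following the
# doubling rule for the Mann-Whitney U statistic.
wilcox_exact_oracle <- function(a, b) {
  na <- length(a)
  x <- c(a, b)
  r <- rank(x)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(x), na)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  pl <- mean(u_all <= u_obs)
  pg <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pg))
}

# Ordinary least squares via the normal equations (independent of lm()).
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Pair-counting adjusted agreement (Hubert-Arabie), from explicit pair
# tallies rather than a contingency table.
ari_oracle <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (sa && !sb) s10 <- s10 + 1
      else if (!sa && sb) s01 <- s01 + 1
      else s00 <- s00 + 1
    }
  }
  num <- 2 * (s11 * s00 - s10 * s01)
  den <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (den == 0) return(1)
  num / den
}

# Planted two-block signed graph fixture: positive within, negative
# between, optional additive symmetric noise.
planted_signed_graph <- function(n = 10, labels = rep(1:2, each = n / 2),
                                 w_in = 0.7, w_out = -0.3, noise_sd = 0,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- ifelse(outer(labels, labels, "=="), w_in, w_out)
  if (noise_sd > 0) {
    E <- matrix(rnorm(n * n, 0, noise_sd), n, n)
    W <- W + (E + t(E)) / 2
  }
  diag(W) <- 1
  W
}

pos_strengths <- function(W) {
  Wp <- pmax(W, 0)
  diag(Wp) <- 0
  rowSums(Wp)
}

neg_strengths <- function(W) {
  Wn <- pmax(-W, 0)
  diag(Wn) <- 0
  rowSums(Wn)
}
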