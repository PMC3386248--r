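# Signed modularity, community detection, null model, Z-scores.

test_that("qstar is zero for the all-in-one partition and matches the oracle", {
  W <- planted_signed_graph(6, rep(1:2, each = 3), 0.8, -0.4)
  expect_equal(qstar(W, rep(1, 6)), 0)

  # two equal-weight triangles, positive within, negative between
  lab <- rep(1:2, each = 3)
  expect_equal(qstar(W, lab), qstar_oracle(W, lab), tolerance = 1e-12)

  # merging the triangles scores strictly lower
  expect_lt(qstar(W, rep(1, 6)), qstar(W, lab))

  # random signed graphs against the direct-summation oracle
  for (seed in 1:5) {
    Wr <- planted_signed_graph(7, c(1, 1, 2, 2, 2, 3, 3), 0.5, -0.2,
                               noise_sd = 0.3, seed = seed)
    labs <- sample(1:3, 7, replace = TRUE)
    expect_equal(qstar(Wr, labs), qstar_oracle(Wr, labs), tolerance = 1e-12)
  }

  expect_error(qstar(matrix(c(1, 2, 0, 1), 2, 2), c(1, 2)), "symmetric")
})

test_that("detect_modules recovers a planted noise-free 2-block structure", {
  W <- planted_signed_graph(12, rep(1:2, each = 6), 0.7, -0.3)
  p <- detect_modules(W, seed = 1)
  expect_equal(p$labels, rep(1:2, each = 6))
  expect_equal(p$n_modules, 2L)
  expect_equal(p$qstar, qstar(W, p$labels))
})

test_that("detect_modules is deterministic under a fixed seed", {
  W <- planted_signed_graph(16, rep(1:4, each = 4), 0.5, -0.2,
                            noise_sd = 0.4, seed = 8)
  p1 <- detect_modules(W, seed = 99)
  p2 <- detect_modules(W, seed = 99)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$qstar, p2$qstar)
})

test_that("detected Q* never falls below the trivial partition", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:12, 1)
    W <- planted_signed_graph(n, sample(1:3, n, replace = TRUE), 0.5, -0.3,
                              noise_sd = 0.5, seed = seed + 100)
    p <- detect_modules(W, seed = seed)
    expect_gte(p$qstar, qstar(W, rep(1, n)) - 1e-12)
  }
  # positive-only graphs: all-in-one partition scores exactly 0
  Wpos <- planted_signed_graph(8, rep(1:2, each = 4), 0.8, 0)
  Wpos[Wpos < 0] <- 0
  expect_identical(qstar(Wpos, rep(1, 8)), 0)
})

test_that("label canonicalization is idempotent and preserves qstar", {
  W <- planted_signed_graph(9, c(2, 2, 2, 1, 1, 1, 3, 3, 3), 0.6, -0.2)
  lab <- c(3L, 3L, 3L, 1L, 1L, 1L, 2L, 2L, 2L)
  can <- canonicalize_labels(lab)
  expect_equal(can, c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L))
  expect_identical(canonicalize_labels(can), can)
  expect_equal(qstar(W, lab), qstar(W, can))
})

test_that("optimizer reaches the exhaustive-enumeration optimum on small graphs", {
  # primary correctness surface: on N <= 8 the detected Q* must match the
  # maximum over all set partitions in at least 95% of seeded instances
  n_instances <- 100
  hits <- 0
  parts_by_n <- list()
  for (inst in seq_len(n_instances)) {
    set.seed(inst)
    n <- sample(4:8, 1)
    k <- sample(2:3, 1)
    lab_true <- sort(sample(seq_len(k), n, replace = TRUE))
    W <- planted_signed_graph(n, lab_true, runif(1, 0.3, 0.8),
                              -runif(1, 0.05, 0.4),
                              noise_sd = runif(1, 0.1, 0.6),
                              seed = inst + 1000)
    key <- as.character(n)
    if (is.null(parts_by_n[[key]])) parts_by_n[[key]] <- enumerate_partitions(n)
    Wp <- pmax(W, 0); diag(Wp) <- 0
    Wn <- pmax(-W, 0); diag(Wn) <- 0
    sp <- rowSums(Wp); sn <- rowSums(Wn)
    vp <- sum(Wp); vn <- sum(Wn)
    best <- max(vapply(parts_by_n[[key]], function(lb) {
      qstar_oracle_fast(Wp, Wn, sp, sn, vp, vn, lb)
    }, numeric(1)))
    det <- detect_modules(W, seed = inst)$qstar
    if (det >= best - 1e-9) hits <- hits + 1
  }
  expect_gte(hits / n_instances, 0.95)
})

test_that("null model preserves weight multisets exactly", {
  W <- planted_signed_graph(15, rep(1:3, each = 5), 0.6, -0.25,
                            noise_sd = 0.2, seed = 3)
  nl <- null_model(W, seed = 7)
  expect_equal(sort(nl$weights[upper.tri(nl$weights)]),
               sort(W[upper.tri(W)]))
  expect_true(isSymmetric(nl$weights))
  expect_equal(diag(nl$weights), rep(1, 15), ignore_attr = TRUE)
})

test_that("null strength sequences track the original (Spearman >= 0.8)", {
  set.seed(2)
  lab <- rep(1:3, times = c(4, 8, 12))
  W <- planted_signed_graph(24, lab, 0.7, -0.25, noise_sd = 0.08, seed = 2)
  for (seed in 1:5) {
    nl <- null_model(W, seed = seed)
    expect_gte(cor(pos_strengths(W), pos_strengths(nl$weights),
                   method = "spearman"), 0.8)
    expect_gte(cor(neg_strengths(W), neg_strengths(nl$weights),
                   method = "spearman"), 0.8)
  }
})

test_that("nulls of a modular graph score well below the original Q*", {
  W <- planted_signed_graph(30, rep(1:3, each = 10), 0.6, -0.25,
                            noise_sd = 0.15, seed = 5)
  q_orig <- detect_modules(W, seed = 1)$qstar
  q_null <- vapply(1:20, function(s) {
    detect_modules(null_model(W, seed = s), seed = s)$qstar
  }, numeric(1))
  expect_lt(median(q_null), q_orig)
})

test_that("a constant-weight graph is unchanged by the null model", {
  W <- matrix(0.4, 12, 12)
  diag(W) <- 1
  nl <- null_model(W, seed = 9)
  expect_equal(nl$weights, W, ignore_attr = TRUE)
  expect_equal(qstar(nl$weights, rep(1:2, each = 6)),
               qstar(W, rep(1:2, each = 6)))
})

test_that("within-module degree Z-scores standardize correctly", {
  # hand-set 5-node example against a direct two-pass mean/sd oracle
  W <- matrix(0, 5, 5)
  W[1, 2] <- 0.9; W[1, 3] <- 0.5; W[2, 3] <- 0.3
  W[4, 5] <- 0.7
  W[1, 4] <- -0.2; W[3, 5] <- -0.4
  W <- W + t(W); diag(W) <- 1
  lab <- c(1, 1, 1, 2, 2)
  z <- within_module_degree_z(W, lab)
  kappa <- c(W[1, 2] + W[1, 3], W[2, 1] + W[2, 3], W[3, 1] + W[3, 2])
  mu <- mean(kappa)
  sdev <- sqrt(mean((kappa - mu)^2))
  expect_equal(z[1:3], (kappa - mu) / sdev, tolerance = 1e-12)
  # two-node module with equal strengths: zero variance -> z = 0
  expect_equal(z[4:5], c(0, 0))

  # standardization identity: within-module mean z is 0
  set.seed(4)
  W2 <- planted_signed_graph(12, rep(1:3, each = 4), 0.6, -0.2,
                             noise_sd = 0.3, seed = 4)
  lab2 <- rep(1:3, each = 4)
  z2 <- within_module_degree_z(W2, lab2)
  for (m in 1:3) expect_equal(mean(z2[lab2 == m]), 0, tolerance = 1e-9)

  # singleton modules get z = 0
  z3 <- within_module_degree_z(W2, c(rep(1, 11), 2))
  expect_equal(z3[12], 0)

  # positive-only mode drops negative weights
  zp <- within_module_degree_z(W2, lab2, weight_mode = "positive")
  W2p <- pmax(W2, 0)
  zp_oracle <- within_module_degree_z(W2p, lab2)
  expect_equal(zp, zp_oracle, tolerance = 1e-12)
})
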