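# Synthetic switching-state BOLD generator.

test_that("state_spec validates labels, correlation ranges and PSD", {
  s <- state_spec(1, rep(1:2, each = 4), 0.6, -0.2)
  expect_s3_class(s, "state_spec")
  expect_equal(dim(s$correlation), c(8, 8))
  expect_error(state_spec(1, c(1, 3, 3), 0.5, -0.1), "contiguous")
  expect_error(state_spec(1, rep(1:2, each = 4), 1.2, -0.1), "rho_in")
  expect_error(state_spec(1, rep(1:2, each = 4), 0.5, 0.1), "rho_out")
  # strongly negative between-block correlation breaks PSD for large blocks
  expect_error(state_spec(1, rep(1:2, each = 20), 0.2, -0.5),
               "positive semi-definite")
})

test_that("generate_state_sequence follows the chain and is reproducible", {
  # absorbing chain: constant sequence, occupancy exactly 1
  sq <- generate_state_sequence(100, diag(2), c(1, 0), seed = 1)
  expect_equal(sq, rep(1L, 100))
  tru <- switching_truth(sq, list(
    state_spec(1, rep(1:2, each = 3), 0.5, -0.2),
    state_spec(2, rep(1:3, each = 2), 0.5, -0.2)
  ))
  expect_equal(unname(tru$occupancy), c(1, 0))

  # T = 1 draws from the initial distribution only
  expect_equal(length(generate_state_sequence(1, diag(2), c(0, 1), seed = 2)), 1L)

  # symmetric 2-state chain with switch probability 0.5: occupancy -> 1/2,
  # verified by an independent tally of the emitted sequence
  P <- matrix(0.5, 2, 2)
  sq <- generate_state_sequence(10000, P, c(0.5, 0.5), seed = 7)
  expect_equal(sum(sq == 1) / 10000, 0.5, tolerance = 0.02 / 0.5)

  expect_identical(
    generate_state_sequence(50, P, c(0.5, 0.5), seed = 3),
    generate_state_sequence(50, P, c(0.5, 0.5), seed = 3)
  )

  # validation errors name the offending row
  bad <- matrix(c(0.5, 0.4, 0.5, 0.5), 2, 2, byrow = TRUE)
  expect_error(generate_state_sequence(10, bad, c(1, 0), 1), "row 1")
})

test_that("occupancy recorded in the truth equals the sequence tally exactly", {
  specs <- list(
    state_spec(1, rep(1:2, each = 3), 0.5, -0.2),
    state_spec(2, rep(1:3, each = 2), 0.5, -0.2)
  )
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  for (seed in 1:5) {
    sq <- generate_state_sequence(37, P, c(0.5, 0.5), seed)
    tru <- switching_truth(sq, specs)
    expect_identical(unname(tru$occupancy),
                     c(sum(sq == 1), sum(sq == 2)) / 37)
  }
})

test_that("noise-free single-state series reproduces the planted correlations", {
  lab <- rep(1:2, each = 4)
  spec <- state_spec(1, lab, 0.8, -0.3)
  tru <- switching_truth(rep(1L, 5000), list(spec))
  ts <- generate_bold(tru, noise_sd = 0, smoothing_halfwidth = 0, seed = 42)
  C <- cor(ts$data)
  within <- C[outer(lab, lab, "==") & upper.tri(C)]
  between <- C[outer(lab, lab, "!=") & upper.tri(C)]
  expect_true(all(abs(within - 0.8) < 0.05))
  expect_true(all(abs(between + 0.3) < 0.05))
})

test_that("heavy noise drives all empirical correlations toward zero", {
  spec <- state_spec(1, rep(1:2, each = 4), 0.8, -0.3)
  tru <- switching_truth(rep(1L, 5000), list(spec))
  ts <- generate_bold(tru, noise_sd = 100, smoothing_halfwidth = 0, seed = 9)
  C <- cor(ts$data)
  expect_true(all(abs(C[upper.tri(C)]) < 0.05))
})

test_that("generation is bit-identical under identical seeds", {
  specs <- default_switching_states(n_regions = 12)
  P <- default_transition()
  tru <- switching_truth(generate_state_sequence(40, P, c(0.5, 0.5), 5), specs)
  a <- generate_bold(tru, seed = 11)
  b <- generate_bold(tru, seed = 11)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, generate_bold(tru, seed = 12)$data))
})

test_that("generate_cohort derives subject seeds deterministically", {
  specs <- default_switching_states(n_regions = 10)
  tabs <- list(A = default_transition(), B = default_transition(0.3, 0.02))
  coh1 <- generate_cohort(c(A = 2, B = 1), specs, tabs, n_volumes = 30, seed = 4)
  coh2 <- generate_cohort(c(A = 2, B = 1), specs, tabs, n_volumes = 30, seed = 4)
  expect_length(coh1, 3)
  expect_identical(coh1[[1]]$ts$data, coh2[[1]]$ts$data)
  expect_identical(coh1[[3]]$truth$state_sequence,
                   coh2[[3]]$truth$state_sequence)
  # distinct subjects get distinct realizations
  expect_false(identical(coh1[[1]]$ts$data, coh1[[2]]$ts$data))
  # single-subject cohort
  expect_length(generate_cohort(c(A = 1), specs, tabs["A"],
                                n_volumes = 30, seed = 1), 1)
})

test_that("a planted occupancy bias separates the groups consistently", {
  # group B biased toward state 2: its mean state-2 occupancy should exceed
  # group A's in (nearly) every replicate
  specs <- default_switching_states(n_regions = 6)
  tabs <- list(A = default_transition(0.7, 0.05),
               B = default_transition(0.3, 0.05))
  wins <- vapply(1:100, function(r) {
    # 5 subjects per group, occupancy of the anterior-like state
    a <- vapply(1:5, function(s) {
      sq <- generate_state_sequence(100, tabs$A, c(0.7, 0.3), r * 101 + s)
      mean(sq == 2)
    }, numeric(1))
    b <- vapply(1:5, function(s) {
      sq <- generate_state_sequence(100, tabs$B, c(0.3, 0.7), r * 101 + 50 + s)
      mean(sq == 2)
    }, numeric(1))
    mean(b) > mean(a)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
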