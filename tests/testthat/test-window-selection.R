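# Window-length selection and power-law extrapolation.

# hand-built curve helper matching the qstar_variance_curve structure
fake_curve <- function(lengths, rel, ref = 50) {
  structure(
    data.frame(length = lengths, sd_qstar = NA_real_,
               relative_variance_pct = rel),
    reference_length = ref,
    class = c("qstar_variance_curve", "data.frame")
  )
}

fake_count_curve <- function(df) {
  structure(df, class = c("module_count_curve", "data.frame"))
}

test_that("select_window returns the smallest odd length under the cutoff", {
  # relative variance crossing 10% between lengths 9 and 11 selects 11
  curve <- fake_curve(c(5, 7, 9, 11, 13, 50), c(80, 40, 15, 8, 5, 0))
  expect_equal(select_window(curve, cutoff_pct = 10), 11)
  # all lengths satisfy the cutoff: smallest odd length wins
  curve2 <- fake_curve(c(9, 11, 50), c(1, 0.5, 0))
  expect_equal(select_window(curve2, cutoff_pct = 10), 9)
  # cutoff 0: first odd length at or below zero, else an explicit error
  curve3 <- fake_curve(c(9, 11, 49, 50), c(12, 4, -1, 0))
  expect_equal(select_window(curve3, cutoff_pct = 0), 49)
  expect_error(select_window(fake_curve(c(9, 11), c(30, 20)), cutoff_pct = 10),
               "no reliable window")
  # monotone in cutoff: a larger cutoff never yields a larger window
  curve4 <- fake_curve(c(7, 9, 11, 13, 50), c(42, 17, 9, 3, 0))
  picks <- vapply(c(3, 9, 15, 20, 45), function(co) {
    select_window(curve4, cutoff_pct = co)
  }, numeric(1))
  expect_true(all(diff(picks) <= 0))
})

test_that("variance curve is exactly zero at the reference length", {
  # degenerate stationary cohort: periodic deterministic signals give
  # identical graphs at every window, so sd(Q*) = 0 at every length
  t <- 0:59
  data <- cbind(sin(2 * pi * t / 5), cos(2 * pi * t / 5),
                sin(4 * pi * t / 5), cos(4 * pi * t / 5),
                sin(6 * pi * t / 5), cos(6 * pi * t / 5))
  ts <- roi_timeseries(data)
  curve <- qstar_variance_curve(list(ts), c(5, 15, 25), seed = 1,
                                n_restarts = 3)
  expect_equal(attr(curve, "reference_length"), 30)
  expect_true(30 %in% curve$length)  # added automatically
  expect_equal(curve$sd_qstar, rep(0, 4), tolerance = 1e-10)
  expect_equal(curve$relative_variance_pct, rep(0, 4))
})

test_that("sd of Q* decreases with window length on a switching cohort", {
  specs <- default_switching_states(n_regions = 16)
  tr <- default_transition()
  coh <- generate_cohort(c(A = 4), specs, list(A = tr), seed = 21,
                         initial_by_group = list(A = c(0.7, 0.3)))
  curve <- qstar_variance_curve(cohort_timeseries(coh), c(11, 21, 31, 41),
                                seed = 2, n_restarts = 5)
  expect_equal(curve$relative_variance_pct[curve$length == 50], 0)
  expect_lt(cor(curve$length, curve$sd_qstar, method = "spearman"), 0)
})

test_that("module count proportions are normalized and track the truth", {
  # single-state 2-block noise-free cohort: every window is 2-modular
  specs2 <- list(state_spec(1, rep(1:2, each = 8), 0.7, -0.2))
  tru <- switching_truth(rep(1L, 60), specs2)
  ts <- generate_bold(tru, noise_sd = 0, seed = 3)
  curve <- module_count_curve(list(ts), c(11, 21), seed = 1, n_restarts = 5)
  for (L in c(11, 21)) {
    sub <- curve[curve$length == L, ]
    expect_equal(sum(sub$proportion), 1, tolerance = 1e-9)
    expect_equal(sub$proportion[sub$n_modules == "2"], 1)
  }
})

test_that("2-module proportion decays with window length under switching", {
  specs <- default_switching_states(n_regions = 16)
  # fast switching so that longer windows straddle states often
  tr <- default_transition(occupancy_1 = 0.5, p_leave_1 = 0.05)
  coh <- generate_cohort(c(A = 4), specs, list(A = tr), seed = 31,
                         initial_by_group = list(A = c(0.5, 0.5)))
  curve <- module_count_curve(cohort_timeseries(coh), c(11, 31, 51),
                              seed = 3, n_restarts = 5)
  p2 <- vapply(c(11, 31, 51), function(L) {
    curve$proportion[curve$length == L & curve$n_modules == "2"]
  }, numeric(1))
  expect_true(all(diff(p2) < 0))
})

test_that("powerlaw_intercept recovers exact and noisy power laws", {
  lengths <- seq(11, 49, by = 2)
  # exact law p(L) = 0.9 * L^-0.5
  df <- data.frame(length = lengths, n_modules = "2",
                   proportion = 0.9 * lengths^-0.5)
  expect_equal(powerlaw_intercept(fake_count_curve(df), lengths), 90,
               tolerance = 1e-9)
  # constant proportion: slope 0, intercept = the constant
  dfc <- data.frame(length = lengths, n_modules = "2", proportion = 0.25)
  expect_equal(powerlaw_intercept(fake_count_curve(dfc), lengths), 25,
               tolerance = 1e-9)
  # noisy law: matches an independent normal-equations OLS fit to 1e-12
  set.seed(12)
  noisy <- 0.8 * lengths^-0.4 * exp(rnorm(length(lengths), 0, 0.1))
  dfn <- data.frame(length = lengths, n_modules = "2", proportion = noisy)
  got <- powerlaw_intercept(fake_count_curve(dfn), lengths)
  beta <- ols_oracle(log10(lengths), log10(noisy))
  expect_equal(got, 100 * 10^unname(beta[1]), tolerance = 1e-12)
  # zero proportions in range are rejected
  dfz <- df; dfz$proportion[3] <- 0
  expect_error(powerlaw_intercept(fake_count_curve(dfz), lengths), "zero")
  # missing lengths are rejected
  expect_error(powerlaw_intercept(fake_count_curve(df), c(lengths, 51)),
               "absent")
})
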