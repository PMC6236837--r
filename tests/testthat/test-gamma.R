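test_that("identical profiles give zero gamma and a 100% pass rate", {
  x <- seq(-5, 5, by = 0.1)
  spec <- beam_spec(5, penumbra_sigma = 0.25)
  scan <- profile_scan(x, open_profile(spec, x))
  for (crit in list(gamma_criteria(1, 1), gamma_criteria(2, 2))) {
    res <- gamma_profile(scan, scan, crit)
    expect_equal(max(res$gamma[res$included]), 0)
    expect_equal(res$pass_rate, 100)
  }
})

test_that("a uniform dose offset on a flat profile gives the closed-form gamma", {
  x <- seq(-4, 4, by = 0.2)
  ref <- profile_scan(x, rep(100, length(x)))
  ev <- profile_scan(x, rep(101, length(x)))
  res <- gamma_profile(ref, ev, gamma_criteria(2, 2))
  expect_equal(unname(res$gamma[res$included]),
               rep(0.5, sum(res$included)), tolerance = 1e-9)
  expect_equal(res$pass_rate, 100)
  # 1% criterion: offset equals the dose tolerance exactly
  res1 <- gamma_profile(ref, ev, gamma_criteria(1, 1))
  expect_equal(unname(res1$gamma[res1$included]),
               rep(1, sum(res1$included)), tolerance = 1e-9)
})

test_that("windowed search matches the exhaustive brute-force oracle", {
  set.seed(101)
  for (rep in 1:60) {
    pair <- random_profile_pair()
    crit <- gamma_criteria(sample(c(1, 2, 3), 1), sample(c(1, 2), 1))
    res <- gamma_profile(pair$reference, pair$evaluated, crit)
    oracle <- gamma_brute_force(pair$reference, pair$evaluated, crit)
    expect_lt(max(abs(res$gamma - oracle), na.rm = TRUE), 1e-6)
    expect_identical(is.na(res$gamma), is.na(oracle))
  }
})

test_that("local-mode gamma also matches the brute-force oracle", {
  set.seed(202)
  for (rep in 1:20) {
    pair <- random_profile_pair()
    crit <- gamma_criteria(2, 2, normalization = "local")
    res <- gamma_profile(pair$reference, pair$evaluated, crit)
    oracle <- gamma_brute_force(pair$reference, pair$evaluated, crit)
    expect_lt(max(abs(res$gamma - oracle), na.rm = TRUE), 1e-6)
  }
})

test_that("tightening criteria never increases the pass rate", {
  set.seed(303)
  for (rep in 1:25) {
    pair <- random_profile_pair()
    loose <- gamma_profile(pair$reference, pair$evaluated,
                           gamma_criteria(2, 2))
    tight <- gamma_profile(pair$reference, pair$evaluated,
                           gamma_criteria(1, 1))
    expect_lte(tight$pass_rate, loose$pass_rate)
  }
})

test_that("gamma is scale-consistent under global normalization", {
  x <- seq(-5, 5, by = 0.1)
  spec <- beam_spec(5, penumbra_sigma = 0.25)
  ref <- profile_scan(x, open_profile(spec, x))
  set.seed(11)
  ev <- profile_scan(x, open_profile(spec, x) *
                       (1 + stats::rnorm(length(x), 0, 0.01)))
  crit <- gamma_criteria(2, 2)
  base <- gamma_profile(ref, ev, crit)
  ref2 <- profile_scan(x, ref$doses * 3.7)
  ev2 <- profile_scan(x, ev$doses * 3.7)
  scaled <- gamma_profile(ref2, ev2, crit)
  expect_lt(max(abs(base$gamma - scaled$gamma), na.rm = TRUE), 1e-9)
})

test_that("a pure spatial shift is bounded by shift over DTA", {
  x <- seq(-6, 6, by = 0.05)
  spec <- beam_spec(5, penumbra_sigma = 0.25)
  ref <- profile_scan(x, open_profile(spec, x))
  s <- 0.1 # cm, half the 2 mm DTA
  ev <- profile_scan(x + s, open_profile(spec, x))
  res <- gamma_profile(ref, ev, gamma_criteria(2, 2))
  expect_lt(max(res$gamma, na.rm = TRUE), s / 0.2 + 0.02)
})

test_that("halving the interpolation step barely changes smooth-profile gamma", {
  # gentle gradients: the grid-sampled minimum sits in a shallow parabola,
  # so refining the dense grid has a second-order effect
  x <- seq(-5, 5, by = 0.1)
  ref <- profile_scan(x, rep(100, length(x)))
  ev <- profile_scan(x, 101 + 0.2 * x)
  g1 <- gamma_profile(ref, ev, gamma_criteria(2, 2, interp_step_mm = 0.04))
  g2 <- gamma_profile(ref, ev, gamma_criteria(2, 2, interp_step_mm = 0.02))
  expect_lt(max(abs(g1$gamma - g2$gamma), na.rm = TRUE), 1e-3)
})

test_that("pass_rate counts included points against the threshold", {
  x <- seq(-4, 4, by = 0.2)
  ref <- profile_scan(x, rep(100, length(x)))
  ev <- profile_scan(x, rep(103, length(x)))
  res <- gamma_profile(ref, ev, gamma_criteria(2, 2)) # all gamma = 1.5
  expect_equal(res$pass_rate, 0)
  expect_equal(pass_rate(res, gamma_threshold = 2), 100)
  expect_equal(pass_rate(res, gamma_threshold = 1.5), 100)
})

test_that("dose difference matches direct point evaluation", {
  ref <- profile_scan(c(-2, 0, 2), c(50, 100, 50))
  same <- dose_difference(ref, ref)
  expect_equal(same$difference, c(0, 0, 0))
  expect_equal(same$mean, 0)
  ev <- profile_scan(c(-3, 3), c(47 - 3, 47 + 3) + c(6, 6))
  # evaluated is the line y = x + 50; offset vs the tent reference
  expected <- (ref$positions + 50 + 3) - ref$doses
  res <- dose_difference(ref, ev, "signed")
  expect_equal(res$difference, expected, tolerance = 1e-9)
  const <- profile_scan(c(-2, 0, 2), c(53, 103, 53))
  expect_equal(dose_difference(ref, const, "absolute")$mean, 3)
  narrow <- profile_scan(c(-1, 1), c(80, 80))
  expect_error(dose_difference(ref, narrow), class = "domain_error")
})

test_that("non-overlapping scans are rejected", {
  a <- profile_scan(c(0, 1), c(100, 100))
  b <- profile_scan(c(5, 6), c(100, 100))
  expect_error(gamma_profile(a, b, gamma_criteria(2, 2)),
               class = "domain_error")
})
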