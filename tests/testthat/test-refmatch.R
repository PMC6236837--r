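test_that("rectangular convolution leaves constants and interior ramps alone", {
  x <- seq(-2, 2, by = 0.05)
  const <- profile_scan(x, rep(77, length(x)))
  expect_equal(convolve_rect(const, 0.4)$doses, const$doses)
  ramp <- profile_scan(x, 50 + 10 * x + 100)
  out <- convolve_rect(ramp, 0.4)
  interior <- abs(x) <= 2 - 0.2
  expect_equal(out$doses[interior], ramp$doses[interior], tolerance = 1e-12)
  expect_equal(out$positions, ramp$positions)
})

test_that("a step edge convolves to the analytic ramp of the kernel width", {
  h <- 0.05
  w <- 0.4
  x <- seq(-2, 2, by = h)
  step <- profile_scan(x, ifelse(x < 0, 0, 1))
  out <- convolve_rect(step, w)
  # the sampled step interpolates as a one-cell ramp centered at -h/2;
  # away from the ramp corners the convolution equals the ideal step ramp
  expected <- step_tophat_expected(x, -h / 2, w)
  away_from_corners <- abs(abs(x + h / 2) - w / 2) >= h
  expect_true(sum(away_from_corners) > length(x) - 20)
  expect_lt(max(abs(out$doses[away_from_corners] -
                      expected[away_from_corners])), 1e-9)
  # the transition spans exactly the kernel width around the edge
  expect_true(all(out$doses[x <= -h / 2 - w / 2 - h] == 0))
  expect_true(all(out$doses[x >= -h / 2 + w / 2 + h] == 1))
})

test_that("convolution is bounded by the input dose range and near-identity for tiny widths", {
  x <- seq(-3, 3, by = 0.05)
  spec <- beam_spec(4, penumbra_sigma = 0.2)
  scan <- profile_scan(x, open_profile(spec, x))
  out <- convolve_rect(scan, 0.4)
  expect_gte(min(out$doses), min(scan$doses) - 1e-9)
  expect_lte(max(out$doses), max(scan$doses) + 1e-9)
  expect_equal(convolve_rect(scan, 0.01)$doses, scan$doses)
})

test_that("convolution validates width and sampling density", {
  x <- seq(-2, 2, by = 0.2)
  scan <- profile_scan(x, 100 - x^2)
  expect_error(convolve_rect(scan, -1), class = "invalid_parameter")
  expect_error(convolve_rect(scan, 0.4), class = "resolution_error")
  irregular <- profile_scan(c(0, 0.1, 0.15, 0.3), c(1, 2, 3, 4))
  expect_error(convolve_rect(irregular, 0.4), class = "resolution_error")
})

test_that("resampling interpolates linearly and is exact on its own grid", {
  scan <- profile_scan(c(0, 1, 2), c(10, 20, 10))
  expect_equal(resample(scan, c(0, 1, 2))$doses, scan$doses)
  expect_equal(resample(scan, 0.5)$doses, 15)
  # dense resample then decimate back is exact on piecewise-linear data
  dense <- resample(scan, seq(0, 2, by = 0.01))
  back <- resample(dense, c(0, 1, 2))
  expect_equal(back$doses, scan$doses, tolerance = 1e-12)
  expect_error(resample(scan, 2.5), class = "domain_error")
  # monotone data stays monotone
  mono <- profile_scan(0:5, c(1, 3, 4, 8, 9, 12))
  out <- resample(mono, seq(0, 5, by = 0.1))
  expect_true(all(diff(out$doses) >= 0))
})

test_that("detector-size matching raises the gamma pass rate on a small field", {
  # volume-averaged array readings vs a sharp reference: convolving the
  # reference with the chamber width recovers agreement in the penumbra.
  # The sharpest condition — 2 x 2 cm at d_max, diode-grade penumbra —
  # is where the mismatch is resolvable. A 0.4 cm top-hat can displace a
  # monotone edge laterally by at most 0.2 cm, inside a 2 mm DTA, so on
  # noiseless profiles the effect shows at 1%/1 mm and the 2%/2 mm rate
  # can only stay equal or improve.
  spec <- beam_spec(2, 100, 1.5, penumbra_sigma = 0.08)
  f <- beam_profile_fun(spec)
  geo <- array_geometry("Y-inline", chamber_width = 0.4)
  acqs <- lapply(0:9, function(k) {
    acquire(f, couch_state(y_shift = 0.05 * k), geo, noise_cov = 0)
  })
  comp <- renormalize(interleave(acqs))
  x <- seq(min(comp$positions) - 0.5, max(comp$positions) + 0.5, by = 0.05)
  sharp <- profile_scan(x, f(x))
  conv <- convolve_rect(sharp, 0.4)
  keep <- function(s) {
    sel <- s$positions >= min(comp$positions) &
      s$positions <= max(comp$positions)
    renormalize(profile_scan(s$positions[sel], s$doses[sel],
                             meta = list(composite_spacing_cm = 0.05)))
  }
  tight <- gamma_criteria(1, 1)
  before <- gamma_profile(keep(sharp), comp, tight)$pass_rate
  after <- gamma_profile(keep(conv), comp, tight)$pass_rate
  expect_gt(after, before)
  expect_equal(after, 100)
  loose <- gamma_criteria(2, 2)
  before2 <- gamma_profile(keep(sharp), comp, loose)$pass_rate
  after2 <- gamma_profile(keep(conv), comp, loose)$pass_rate
  expect_gte(after2, before2)
})
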