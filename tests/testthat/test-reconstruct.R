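test_that("couch shifts map the array into the fixed frame with opposite sign", {
  # +0.1 cm lateral couch shift puts the central detector at -0.1 cm
  expect_equal(to_fixed_frame(c(0, 0), couch_state(x_shift = 0.1)),
               c(-0.1, 0))
  # longitudinal 147.5 -> 147.9 cm, i.e. a +0.4 cm shift, lands at -0.4 cm
  expect_equal(to_fixed_frame(c(0, 0), couch_state(y_shift = 147.9 - 147.5)),
               c(0, -0.4))
  expect_equal(to_fixed_frame(c(1.25, -2), couch_state()), c(1.25, -2))
})

test_that("the 90-degree transform agrees with a rotation-matrix oracle", {
  rot90 <- matrix(c(0, 1, -1, 0), 2, 2)
  for (p in c(-1.5, 0.25, 2)) {
    for (dx in c(0, 0.1)) {
      got <- to_fixed_frame(c(p, 0), couch_state(x_shift = dx,
                                                 rotation_deg = 90))
      expect_equal(got, as.numeric(rot90 %*% c(p - dx, 0)))
      # a point on the rotated lateral axis lands where the 0-degree
      # transform puts it on the longitudinal axis
      expect_equal(got,
                   to_fixed_frame(c(0, p - dx), couch_state()))
    }
  }
})

test_that("interleaving sub-pitch shifts yields the composite spacing", {
  f <- beam_profile_fun(small_field_spec())
  geo <- array_geometry("Y-inline", chamber_width = 0)
  acqs <- lapply(0:4, function(k) {
    acquire(f, couch_state(y_shift = 0.1 * k), geo)
  })
  comp <- interleave(acqs)
  expect_equal(comp$meta$composite_spacing_cm, 0.1)
  expect_true(all(diff(comp$positions) > 0))
  # order-independence
  shuffled <- interleave(acqs[c(3, 1, 5, 2, 4)])
  expect_equal(shuffled$positions, comp$positions)
  expect_equal(shuffled$doses, comp$doses)
  # single acquisition passes through at the native pitch
  single <- interleave(acqs[1])
  expect_equal(single$meta$composite_spacing_cm, 0.5)
  expect_length(single$positions, 65)
})

test_that("interleave rejects revisited positions and mixed geometries", {
  f <- beam_profile_fun(small_field_spec())
  geo <- array_geometry("Y-inline")
  a0 <- acquire(f, couch_state(), geo)
  expect_error(interleave(list(a0, a0)), class = "position_collision")
  other <- acquire(f, couch_state(), array_geometry("Y-inline", pitch = 0.4))
  expect_error(interleave(list(a0, other)),
               class = "incompatible_geometry")
})

test_that("renormalization pins the CAX at 100 and preserves ratios", {
  x <- seq(-5, 5, by = 0.1)
  spec <- beam_spec(10, wedge_gradient = 0.05)
  scan <- profile_scan(x, wedge_profile(spec, x) * 0.37,
                       meta = list(composite_spacing_cm = 0.1))
  out <- renormalize(scan)
  expect_equal(stats::approx(out$positions, out$doses, xout = 0)$y, 100)
  expect_equal(out$doses / scan$doses,
               rep(out$doses[1] / scan$doses[1], length(x)))
  # idempotent on an already-normalized scan, and scale-invariant
  expect_equal(renormalize(out)$doses, out$doses)
  doubled <- scan
  doubled$doses <- scan$doses * 2
  expect_equal(renormalize(doubled)$doses, out$doses)
  # max mode for off-axis maxima
  expect_equal(max(renormalize(scan, "max")$doses), 100)
  off_cax <- profile_scan(x + 7, scan$doses,
                          meta = list(composite_spacing_cm = 0.1))
  expect_error(renormalize(off_cax), class = "normalization_error")
})

test_that("distance rescaling applies the SDD ratio and inverts exactly", {
  scan <- profile_scan(c(-10, 0, 10), c(50, 100, 50),
                       meta = list(depth_cm = 5,
                                   composite_spacing_cm = 10))
  out <- rescale_distances(scan, 75, 105)
  expect_equal(out$positions, c(-14, 0, 14))
  expect_equal(out$doses, scan$doses)
  expect_equal(out$meta$ssd_cm, 100)
  back <- rescale_distances(out, 105, 75)
  expect_equal(back$positions, scan$positions)
  expect_equal(rescale_distances(scan, 90, 90)$positions, scan$positions)
  expect_error(rescale_distances(scan, 0, 105),
               class = "invalid_parameter")
})

test_that("effective depth adds slab, inherent buildup, and EPOM shift", {
  expect_equal(effective_depth(4.1), 5.0)
  expect_equal(effective_depth(0), 0.9)
  expect_equal(effective_depth(5, 0, 0), 5.0)
  expect_equal(effective_depth(4, 0.9, 0.1), 5.0)
  expect_error(effective_depth(-1), class = "invalid_parameter")
})

test_that("noiseless zero-width acquisition round-trips the analytic profile", {
  spec <- small_field_spec()
  f <- beam_profile_fun(spec)
  geo <- array_geometry("Y-inline", chamber_width = 0)
  acqs <- lapply(0:4, function(k) {
    acquire(f, couch_state(y_shift = 0.1 * k), geo, noise_cov = 0)
  })
  comp <- renormalize(interleave(acqs))
  truth <- f(comp$positions)
  expect_lt(max(abs(comp$doses - truth) / truth), 1e-9)
})
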