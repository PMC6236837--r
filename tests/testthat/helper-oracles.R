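# Shared fixtures and independent oracles for the test suite.

# Small open-field beam used throughout: 2 x 2 cm at 100 SSD, 5 cm depth.
small_field_spec <- function(...) {
  beam_spec(field_width_iso = 2, ssd = 100, depth = 5,
            penumbra_sigma = 0.15, ...)
}

# Exhaustive brute-force 1D gamma: densely interpolate the evaluated scan
# on the same grid the engine uses and minimize over EVERY dense point,
# with no search window. Independent of the windowed implementation.
gamma_brute_force <- function(reference, evaluated, criteria) {
  dta_cm <- criteria$dta_mm / 10
  step_cm <- criteria$interp_step_mm / 10
  emin <- min(evaluated$positions)
  emax <- max(evaluated$positions)
  grid <- seq(emin, emax, by = step_cm)
  if (grid[length(grid)] < emax - 1e-12) grid <- c(grid, emax)
  dense <- stats::approx(evaluated$positions, evaluated$doses,
                         xout = grid)$y
  p <- reference$positions
  norm <- if (0 >= p[1] && 0 <= p[length(p)]) {
    stats::approx(p, reference$doses, xout = 0)$y
  } else {
    max(reference$doses)
  }
  vapply(seq_along(p), function(i) {
    if (p[i] < emin - 1e-12 || p[i] > emax + 1e-12) return(NA_real_)
    dd <- if (criteria$normalization == "global") {
      criteria$dose_pct / 100 * norm
    } else {
      criteria$dose_pct / 100 * reference$doses[i]
    }
    min(sqrt(((grid - p[i]) / dta_cm)^2 +
               ((dense - reference$doses[i]) / dd)^2))
  }, numeric(1))
}

# Random piecewise-linear profile pair for gamma oracle comparisons:
# strictly increasing positions spanning zero, positive doses.
random_profile_pair <- function(n_ref = 20, n_eval = 20) {
  mk <- function(n) {
    pos <- sort(stats::runif(n, -3, 3))
    pos[1] <- -3
    pos[n] <- 3
    profile_scan(pos, stats::runif(n, 5, 120))
  }
  list(reference = mk(n_ref), evaluated = mk(n_eval))
}

# Analytic convolution of a sampled unit step with a width-w top-hat.
# The sampled step interpolates as a linear ramp over one grid cell
# [edge - h, edge]; away from the ramp corners (by at least h/2) the
# convolution equals the ideal step ramp centered at the cell midpoint.
step_tophat_expected <- function(x, edge_mid, w) {
  pmin(pmax((x - edge_mid + w / 2) / w, 0), 1)
}
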