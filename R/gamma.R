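#' Gamma comparison criteria
#'
#' Tolerance settings for the 1D gamma-index comparison of an evaluated scan
#' against a reference scan: a dose-difference criterion (percent of the
#' normalization dose) and a distance-to-agreement criterion (mm), plus the
#' normalization mode, the low-dose inclusion threshold, and the numerical
#' search controls.
#'
#' @param dose_pct Dose-difference criterion, percent (> 0), e.g. 1 or 2.
#' @param dta_mm Distance-to-agreement criterion, mm (> 0), e.g. 1 or 2.
#' @param normalization `"global"` (dose criterion relative to the reference
#'   CAX dose) or `"local"` (relative to each reference point's dose).
#' @param low_dose_threshold_pct Reference points below this percent of the
#'   normalization dose are excluded (default 0 = include all points).
#' @param search_window_mm Initial half-width of the spatial search window,
#'   mm (default `3 * dta_mm`). The window grows automatically whenever the
#'   bound could affect the minimum, so it never changes the result.
#' @param interp_step_mm Step of the dense evaluated-profile interpolation,
#'   mm (default `dta_mm / 50`); must be smaller than `dta_mm`.
#' @return An object of class `gamma_criteria`.
#' @examples
#' gamma_criteria(2, 2)   # the 2%/2 mm criterion
#' @export
gamma_criteria <- function(dose_pct, dta_mm,
                           normalization = c("global", "local"),
                           low_dose_threshold_pct = 0,
                           search_window_mm = 3 * dta_mm,
                           interp_step_mm = dta_mm / 50) {
  normalization <- match.arg(normalization)
  if (!is.finite(dose_pct) || dose_pct <= 0) {
    stop_compscan("'dose_pct' must be > 0", "invalid_parameter")
  }
  if (!is.finite(dta_mm) || dta_mm <= 0) {
    stop_compscan("'dta_mm' must be > 0", "invalid_parameter")
  }
  if (!is.finite(low_dose_threshold_pct) || low_dose_threshold_pct < 0) {
    stop_compscan("'low_dose_threshold_pct' must be >= 0",
                  "invalid_parameter")
  }
  if (!is.finite(interp_step_mm) || interp_step_mm <= 0 ||
      interp_step_mm >= dta_mm) {
    stop_compscan("'interp_step_mm' must lie in (0, dta_mm)",
                  "invalid_parameter")
  }
  if (!is.finite(search_window_mm) || search_window_mm <= 0) {
    stop_compscan("'search_window_mm' must be > 0", "invalid_parameter")
  }
  structure(
    list(dose_pct = dose_pct, dta_mm = dta_mm,
         normalization = normalization,
         low_dose_threshold_pct = low_dose_threshold_pct,
         search_window_mm = search_window_mm,
         interp_step_mm = interp_step_mm),
    class = "gamma_criteria"
  )
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %g%%/%g mm, %s normalization, threshold %g%%\n",
              x$dose_pct, x$dta_mm, x$normalization,
              x$low_dose_threshold_pct))
  invisible(x)
}

# Global normalization dose of a reference scan: the CAX dose when the CAX
# lies inside the scan, otherwise the maximum.
reference_norm_dose <- function(reference) {
  p <- reference$positions
  if (0 >= p[1] && 0 <= p[length(p)]) {
    stats::approx(p, reference$doses, xout = 0)$y
  } else {
    max(reference$doses)
  }
}

#' 1D gamma-index comparison of two profile scans
#'
#' Computes the gamma index at every reference point: the minimum over a
#' densely interpolated evaluated profile of
#' `sqrt(((pos_e - pos_r)/dta)^2 + ((D_e - D_r)/dD)^2)`, where `dta` is the
#' distance-to-agreement criterion and `dD` is `dose_pct` percent of the
#' global normalization dose (global mode) or of the reference point's own
#' dose (local mode). The evaluated profile is linearly interpolated on a
#' grid of step `interp_step_mm`; the spatial search window starts at
#' `search_window_mm` and is widened whenever the candidate minimum exceeds
#' the window's own spatial bound, so the reported gamma is the global
#' minimum over the whole evaluated scan.
#'
#' Reference points below the low-dose threshold, or outside the evaluated
#' scan's position support, are flagged as excluded and get `NA` gamma.
#'
#' @param reference Reference [profile_scan()] (e.g. a dense tank-style scan).
#' @param evaluated Evaluated [profile_scan()] (e.g. a composite array scan).
#' @param criteria A [gamma_criteria()].
#' @return An object of class `gamma_result` with fields `positions`,
#'   `gamma`, `included`, `criteria`, `norm_dose`, `pass_rate` (percent of
#'   included points with gamma <= 1).
#' @examples
#' ref <- profile_scan(seq(-5, 5, 0.1), 100 - abs(seq(-5, 5, 0.1)))
#' res <- gamma_profile(ref, ref, gamma_criteria(2, 2))
#' res$pass_rate  # 100
#' @export
gamma_profile <- function(reference, evaluated, criteria) {
  stopifnot(inherits(reference, "profile_scan"),
            inherits(evaluated, "profile_scan"),
            inherits(criteria, "gamma_criteria"))
  if (max(evaluated$positions) < min(reference$positions) ||
      min(evaluated$positions) > max(reference$positions)) {
    stop_compscan("reference and evaluated scans do not overlap in position",
                  "domain_error")
  }
  dta_cm <- criteria$dta_mm / 10
  step_cm <- criteria$interp_step_mm / 10
  emin <- min(evaluated$positions)
  emax <- max(evaluated$positions)
  grid <- seq(emin, emax, by = step_cm)
  if (grid[length(grid)] < emax - 1e-12) {
    grid <- c(grid, emax)
  }
  dense <- if (length(evaluated$positions) == 1L) {
    rep(evaluated$doses, length(grid))
  } else {
    stats::approx(evaluated$positions, evaluated$doses, xout = grid)$y
  }

  norm_dose <- reference_norm_dose(reference)
  if (!is.finite(norm_dose) || norm_dose <= 0) {
    stop_compscan("normalization dose is not positive", "normalization_error")
  }

  n <- length(reference$positions)
  included <- reference$positions >= emin - 1e-12 &
    reference$positions <= emax + 1e-12
  if (criteria$low_dose_threshold_pct > 0) {
    thr <- criteria$low_dose_threshold_pct / 100 * norm_dose
    included <- included & reference$doses >= thr
  }
  gam <- rep(NA_real_, n)
  win0 <- criteria$search_window_mm / 10
  full_span <- emax - emin
  for (i in which(included)) {
    pr <- reference$positions[i]
    dr <- reference$doses[i]
    dd <- if (criteria$normalization == "global") {
      criteria$dose_pct / 100 * norm_dose
    } else {
      criteria$dose_pct / 100 * dr
    }
    if (!is.finite(dd) || dd <= 0) {
      stop_compscan("local normalization dose is not positive at a reference point",
                    "normalization_error")
    }
    win <- win0
    repeat {
      lo <- findInterval(pr - win, grid) # candidates within +/- win of pr
      hi <- findInterval(pr + win, grid)
      lo <- max(1L, lo)
      hi <- min(length(grid), hi + 1L)
      sel <- lo:hi
      g <- sqrt(((grid[sel] - pr) / dta_cm)^2 + ((dense[sel] - dr) / dd)^2)
      best <- min(g)
      # any point farther than best * dta has gamma >= best, so the window
      # bound is safe once win/dta >= best
      if (best <= win / dta_cm || win >= full_span + abs(pr) + dta_cm) {
        break
      }
      win <- max(2 * win, best * dta_cm)
    }
    gam[i] <- best
  }
  if (!any(included)) {
    stop_compscan("no reference points are included in the comparison",
                  "domain_error")
  }
  res <- structure(
    list(positions = reference$positions, gamma = gam, included = included,
         criteria = criteria, norm_dose = norm_dose),
    class = "gamma_result"
  )
  res$pass_rate <- pass_rate(res)
  res
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %g%%/%g mm: pass rate %.2f%% (%d of %d points included)\n",
    x$criteria$dose_pct, x$criteria$dta_mm, x$pass_rate,
    sum(x$included), length(x$included)))
  invisible(x)
}

#' Gamma pass rate
#'
#' Percentage of included reference points whose gamma does not exceed the
#' threshold.
#'
#' @param result A [gamma_result] from [gamma_profile()].
#' @param gamma_threshold Pass threshold (default 1).
#' @return Pass rate in percent.
#' @export
pass_rate <- function(result, gamma_threshold = 1) {
  stopifnot(inherits(result, "gamma_result"))
  g <- result$gamma[result$included]
  if (length(g) == 0L) {
    stop_compscan("no included points: pass rate undefined",
                  "undefined_rate")
  }
  100 * mean(g <= gamma_threshold)
}

#' Point-by-point dose difference between two scans
#'
#' Linearly interpolates the evaluated scan at every reference position and
#' returns the per-point difference `D_eval - D_ref` (signed) or its
#' absolute value, together with the arithmetic mean. All reference
#' positions must lie within the evaluated scan's support.
#'
#' @param reference Reference [profile_scan()].
#' @param evaluated Evaluated [profile_scan()].
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return List with `positions`, `difference` (per point) and `mean`.
#' @export
dose_difference <- function(reference, evaluated,
                            mode = c("signed", "absolute")) {
  stopifnot(inherits(reference, "profile_scan"),
            inherits(evaluated, "profile_scan"))
  mode <- match.arg(mode)
  emin <- min(evaluated$positions)
  emax <- max(evaluated$positions)
  if (any(reference$positions < emin - 1e-12 |
          reference$positions > emax + 1e-12)) {
    stop_compscan("evaluated scan does not cover every reference position",
                  "domain_error")
  }
  ev <- stats::approx(evaluated$positions, evaluated$doses,
                      xout = reference$positions, rule = 2)$y
  d <- ev - reference$doses
  if (mode == "absolute") {
    d <- abs(d)
  }
  list(positions = reference$positions, difference = d, mean = mean(d))
}
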