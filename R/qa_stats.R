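#' Type A repeatability: per-detector coefficient of variation
#'
#' Given repeated acquisitions taken under an identical setup (same couch
#' state, geometry, and beam), computes each detector's coefficient of
#' variation — sample standard deviation divided by mean, in percent —
#' across the repeats, and the average COV over the in-field detectors. A
#' detector is in-field when its mean reading is at least `infield_rule`
#' times the central-axis mean reading (the detector nearest position 0).
#'
#' @param repeats List of [acquire()] results with identical couch states
#'   and geometries.
#' @param infield_rule In-field threshold as a fraction of the CAX mean
#'   reading (default 0.8).
#' @param n_required Minimum number of repeats (default 5, never below 2).
#' @return List with `indices`, `positions`, `cov_pct` (per detector),
#'   `infield` (logical), `infield_avg_cov` (percent), `n_repeats`.
#' @export
type_a_cov <- function(repeats, infield_rule = 0.8, n_required = 5) {
  if (!is.list(repeats) ||
      !all(vapply(repeats, inherits, logical(1), "array_acquisition"))) {
    stop_compscan("'repeats' must be a list of array_acquisition",
                  "invalid_parameter")
  }
  n <- length(repeats)
  if (n < max(2L, n_required)) {
    stop_compscan(sprintf("at least %d repeats are required",
                          max(2L, n_required)),
                  "invalid_parameter")
  }
  c0 <- repeats[[1]]$couch
  g0 <- repeats[[1]]$geometry
  ok <- vapply(repeats, function(a) {
    isTRUE(all.equal(a$couch$x_shift, c0$x_shift)) &&
      isTRUE(all.equal(a$couch$y_shift, c0$y_shift)) &&
      a$couch$rotation_deg == c0$rotation_deg &&
      identical(a$geometry$axis_label, g0$axis_label) &&
      identical(a$geometry$index_range, g0$index_range)
  }, logical(1))
  if (!all(ok)) {
    stop_compscan("repeats mix couch states or geometries",
                  "incompatible_setup")
  }
  mat <- vapply(repeats, function(a) unname(a$readings),
                numeric(length(repeats[[1]]$readings)))
  means <- rowMeans(mat)
  if (any(means == 0)) {
    stop_compscan("a detector has zero mean reading: COV undefined",
                  "undefined_cov")
  }
  sds <- apply(mat, 1, stats::sd)
  cov_pct <- 100 * sds / means
  pos <- acquisition_positions(g0, c0)
  cax_mean <- means[which.min(abs(pos))]
  infield <- means >= infield_rule * cax_mean
  list(
    indices = repeats[[1]]$indices,
    positions = pos,
    cov_pct = cov_pct,
    infield = infield,
    infield_avg_cov = mean(cov_pct[infield]),
    n_repeats = n
  )
}

#' Couch-shift positioning QA statistic
#'
#' Compares the increments between successive measured positions with the
#' increments between successive nominal shifts: deviations are
#' `diff(measured) - diff(nominal)`. A constant offset between the measured
#' and nominal position scales cancels in the differences, so the statistic
#' isolates the couch's shift accuracy.
#'
#' @param nominal_shifts Nominal couch shift positions (cm), length >= 2.
#' @param measured_positions Measured positions (cm), same length.
#' @return List with `deviations` (cm), `mean`, `sd` (sample), `max_abs`.
#' @examples
#' couch_shift_qa(c(0, 0.1, 0.2), c(0, 0.12, 0.19))
#' @export
couch_shift_qa <- function(nominal_shifts, measured_positions) {
  if (length(nominal_shifts) != length(measured_positions)) {
    stop_compscan("nominal and measured vectors must have equal length",
                  "incompatible_lengths")
  }
  if (length(nominal_shifts) < 2L) {
    stop_compscan("at least two positions are required",
                  "invalid_parameter")
  }
  dev <- diff(measured_positions) - diff(nominal_shifts)
  list(
    deviations = dev,
    mean = mean(dev),
    sd = if (length(dev) > 1L) stats::sd(dev) else 0,
    max_abs = max(abs(dev))
  )
}

#' Sampled-points increase factor
#'
#' Ratio of composite sampling density to the array's native density:
#' `pitch / composite_spacing`. Unlike [mu_budget()], the ratio need not be
#' an integer — a 0.2 cm composite from a 0.5 cm pitch samples 2.5 times as
#' many points per unit length.
#'
#' @param pitch Native detector spacing (cm, > 0).
#' @param composite_spacing Composite point spacing (cm, > 0).
#' @return The dimensionless density ratio.
#' @examples
#' sampling_factor(0.5, 0.2)  # 2.5
#' @export
sampling_factor <- function(pitch, composite_spacing) {
  if (!is.finite(pitch) || pitch <= 0 ||
      !is.finite(composite_spacing) || composite_spacing <= 0) {
    stop_compscan("'pitch' and 'composite_spacing' must be > 0",
                  "invalid_parameter")
  }
  pitch / composite_spacing
}

#' Monitor-unit budget of a composite scan
#'
#' The number of acquisitions needed to reach a composite point spacing from
#' the array's native pitch (the sampled-points increase factor), and the
#' total MU this costs at a fixed MU per acquisition. A 0.1 cm composite
#' from a 0.5 cm pitch takes 5 acquisitions — 250 MU at 50 MU each, versus
#' roughly 1040 MU for a continuously scanned tank profile.
#'
#' @param pitch Native detector spacing (cm, > 0).
#' @param composite_spacing Target composite point spacing (cm); must divide
#'   the pitch to within 1e-9.
#' @param mu_per_acquisition MU delivered per acquisition (> 0).
#' @return List with `acquisitions`, `sampling_factor`, `total_mu`.
#' @examples
#' mu_budget(0.5, 0.1, 50)  # 5 acquisitions, 250 MU
#' @export
mu_budget <- function(pitch, composite_spacing, mu_per_acquisition) {
  if (!is.finite(pitch) || pitch <= 0 ||
      !is.finite(composite_spacing) || composite_spacing <= 0) {
    stop_compscan("'pitch' and 'composite_spacing' must be > 0",
                  "invalid_parameter")
  }
  if (!is.finite(mu_per_acquisition) || mu_per_acquisition <= 0) {
    stop_compscan("'mu_per_acquisition' must be > 0", "invalid_parameter")
  }
  ratio <- pitch / composite_spacing
  if (abs(ratio - round(ratio)) > 1e-9 * max(1, ratio)) {
    stop_compscan("'composite_spacing' must divide 'pitch' evenly",
                  "invalid_parameter")
  }
  count <- as.integer(round(ratio))
  list(
    acquisitions = count,
    sampling_factor = ratio,
    total_mu = count * mu_per_acquisition
  )
}
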