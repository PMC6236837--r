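#' Ordered profile scan
#'
#' The common currency of all pipeline stages: an ordered series of
#' (position, relative dose) samples in the fixed isocenter frame, with axis
#' and geometry metadata. Positions must be strictly increasing and doses
#' non-negative.
#'
#' @param positions Strictly increasing positions (cm, fixed frame).
#' @param doses Relative dose values, same length, all >= 0.
#' @param axis_label Scan axis label (free text, e.g. `"X-crossline"`).
#' @param meta Named list of metadata; recognized entries are
#'   `field_width_iso_cm`, `ssd_cm`, `depth_cm`, `energy`, `normalization`,
#'   `composite_spacing_cm`. Unknown entries are preserved.
#' @return An object of class `profile_scan`.
#' @export
profile_scan <- function(positions, doses, axis_label = "X-crossline",
                         meta = list()) {
  positions <- as.numeric(positions)
  doses <- as.numeric(doses)
  if (length(positions) != length(doses)) {
    stop_compscan("'positions' and 'doses' must have equal length",
                  "invalid_parameter")
  }
  if (length(positions) == 0L) {
    stop_compscan("a profile scan needs at least one point",
                  "invalid_parameter")
  }
  if (any(!is.finite(positions)) || any(!is.finite(doses))) {
    stop_compscan("positions and doses must be finite", "invalid_parameter")
  }
  if (any(diff(positions) <= 0)) {
    stop_compscan("'positions' must be strictly increasing",
                  "invalid_parameter")
  }
  if (any(doses < 0)) {
    stop_compscan("'doses' must be non-negative", "invalid_parameter")
  }
  structure(
    list(positions = positions, doses = doses,
         axis_label = axis_label, meta = meta),
    class = "profile_scan"
  )
}

#' @export
print.profile_scan <- function(x, ...) {
  cat(sprintf(
    "<profile_scan> %d points on %s, [%g, %g] cm",
    length(x$positions), x$axis_label, min(x$positions), max(x$positions)))
  if (!is.null(x$meta$composite_spacing_cm)) {
    cat(sprintf(", spacing %g cm", x$meta$composite_spacing_cm))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.profile_scan <- function(x, ...) {
  data.frame(position_cm = x$positions, dose_rel = x$doses)
}

#' Transform an array position into the fixed isocenter frame
#'
#' Applies the couch state to a point given in the array's coordinate system
#' and returns its coordinates in the radiation-isocenter (fixed) frame.
#' Shifting the couch by +s displaces the array by -s in the fixed frame, so
#' at 0 degrees `X_F = X_P - x_shift` and `Y_F = Y_P - y_shift`; at 90
#' degrees a standard 90-degree rotation is applied to the shifted position,
#' exchanging the roles of the lateral and longitudinal axes. The transform
#' is exactly invertible for a given couch state.
#'
#' @param array_pos Numeric pair `c(X_P, Y_P)` in cm (array frame).
#' @param couch A [couch_state()] (rotation restricted to 0 or 90 degrees).
#' @return Numeric pair `c(X_F, Y_F)` in cm (fixed frame).
#' @examples
#' to_fixed_frame(c(0, 0), couch_state(x_shift = 0.1))  # c(-0.1, 0)
#' @export
to_fixed_frame <- function(array_pos, couch) {
  stopifnot(inherits(couch, "couch_state"))
  if (length(array_pos) != 2L || any(!is.finite(array_pos))) {
    stop_compscan("'array_pos' must be a finite (X_P, Y_P) pair",
                  "invalid_parameter")
  }
  if (!couch$rotation_deg %in% c(0, 90)) {
    stop_compscan("couch rotation must be 0 or 90 degrees",
                  "unsupported_geometry")
  }
  shifted <- c(array_pos[1] - couch$x_shift, array_pos[2] - couch$y_shift)
  theta <- couch$rotation_deg * pi / 180
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  as.numeric(rot %*% shifted)
}

#' Interleave shifted acquisitions into a composite scan
#'
#' Transforms each acquisition's detector readings into the fixed isocenter
#' frame and merges them into a single composite profile sorted by position.
#' K acquisitions taken at couch-shift increments of `pitch / K` yield a
#' uniform composite spacing of `pitch / K` over the overlap region. The
#' composite spacing recorded in the metadata is the median position gap.
#'
#' @param acquisitions List of [acquire()] results sharing one geometry and
#'   axis.
#' @param collision_tol Positions closer than this (cm) are treated as
#'   revisits of the same point and rejected (default 1e-6).
#' @return A [profile_scan()] of the merged readings (unnormalized).
#' @export
interleave <- function(acquisitions, collision_tol = 1e-6) {
  if (!is.list(acquisitions) || length(acquisitions) < 1L ||
      !all(vapply(acquisitions, inherits, logical(1), "array_acquisition"))) {
    stop_compscan("'acquisitions' must be a non-empty list of array_acquisition",
                  "invalid_parameter")
  }
  g0 <- acquisitions[[1]]$geometry
  same <- vapply(acquisitions, function(a) {
    identical(a$geometry$axis_label, g0$axis_label) &&
      isTRUE(all.equal(a$geometry$pitch, g0$pitch)) &&
      identical(a$geometry$index_range, g0$index_range) &&
      identical(a$geometry$central_index, g0$central_index) &&
      identical(a$geometry$missing_indices, g0$missing_indices)
  }, logical(1))
  if (!all(same)) {
    stop_compscan("acquisitions mix incompatible array geometries or axes",
                  "incompatible_geometry")
  }
  pos <- unlist(lapply(acquisitions, function(a) {
    acquisition_positions(a$geometry, a$couch)
  }))
  dose <- unlist(lapply(acquisitions, function(a) unname(a$readings)))
  ord <- order(pos)
  pos <- pos[ord]
  dose <- dose[ord]
  gaps <- diff(pos)
  if (any(gaps < collision_tol)) {
    stop_compscan(
      sprintf("fixed-frame position collision (gap < %g cm); the protocol never revisits a position",
              collision_tol),
      "position_collision")
  }
  spacing <- if (length(gaps)) stats::median(gaps) else g0$pitch
  profile_scan(pos, dose, axis_label = g0$axis_label,
               meta = list(composite_spacing_cm = spacing))
}

#' Renormalize a profile scan
#'
#' Rescales the dose axis so the central-axis value (mode `"cax"`, dose
#' linearly interpolated at position 0) or the maximum value (mode `"max"`,
#' for wedged profiles whose maximum is off-axis) equals 100. Positions and
#' point order are unchanged.
#'
#' @param scan A [profile_scan()].
#' @param mode `"cax"` (default) or `"max"`.
#' @return The renormalized [profile_scan()].
#' @export
renormalize <- function(scan, mode = c("cax", "max")) {
  stopifnot(inherits(scan, "profile_scan"))
  mode <- match.arg(mode)
  if (mode == "cax") {
    spacing <- scan$meta$composite_spacing_cm
    if (is.null(spacing)) {
      spacing <- stats::median(diff(scan$positions))
    }
    if (min(abs(scan$positions)) > spacing / 2 + 1e-12) {
      stop_compscan("no data within half the composite spacing of the CAX",
                    "normalization_error")
    }
    ref <- if (length(scan$positions) == 1L) {
      scan$doses[1]
    } else if (0 >= scan$positions[1] &&
               0 <= scan$positions[length(scan$positions)]) {
      stats::approx(scan$positions, scan$doses, xout = 0, rule = 1)$y
    } else {
      scan$doses[which.min(abs(scan$positions))]
    }
  } else {
    ref <- max(scan$doses)
  }
  if (!is.finite(ref) || ref <= 0) {
    stop_compscan("normalization dose is not positive", "normalization_error")
  }
  out <- scan
  out$doses <- scan$doses * (100 / ref)
  out$meta$normalization <- if (mode == "cax") "CAX=100" else "max=100"
  out
}

#' Rescale scan distances between source-detector distances
#'
#' Multiplies every position by `target_sdd / measured_sdd` to project a
#' profile measured at one source-detector distance onto another, e.g. the
#' 105/75 factor that maps a 70 cm SSD, 5 cm depth composite onto the
#' 100 cm SSD, 5 cm depth reference plane. Doses are unchanged.
#'
#' @param scan A [profile_scan()].
#' @param measured_sdd Source-detector distance of the measurement (cm, > 0).
#' @param target_sdd Source-detector distance to project onto (cm, > 0).
#' @return The rescaled [profile_scan()]; metadata `ssd_cm` is updated to
#'   `target_sdd - depth` when the depth is recorded.
#' @examples
#' s <- profile_scan(c(-10, 0, 10), c(50, 100, 50))
#' rescale_distances(s, 75, 105)$positions  # -14, 0, 14
#' @export
rescale_distances <- function(scan, measured_sdd, target_sdd) {
  stopifnot(inherits(scan, "profile_scan"))
  if (!is.finite(measured_sdd) || measured_sdd <= 0 ||
      !is.finite(target_sdd) || target_sdd <= 0) {
    stop_compscan("source-detector distances must be > 0",
                  "invalid_parameter")
  }
  factor <- target_sdd / measured_sdd
  out <- scan
  out$positions <- scan$positions * factor
  if (!is.null(scan$meta$composite_spacing_cm)) {
    out$meta$composite_spacing_cm <- scan$meta$composite_spacing_cm * factor
  }
  if (!is.null(scan$meta$depth_cm)) {
    out$meta$ssd_cm <- target_sdd - scan$meta$depth_cm
  }
  out
}

#' Water-equivalent effective measurement depth
#'
#' The depth recorded with an array measurement is the solid-water slab
#' thickness above the array plus the array's inherent buildup (0.9 cm of
#' water-equivalent material above the chamber plane) plus any shift to the
#' chambers' effective point of measurement.
#'
#' @param slab_thickness Solid-water thickness above the array (cm, >= 0).
#' @param inherent_buildup Water-equivalent buildup of the array itself
#'   (cm, default 0.9).
#' @param epom_shift Effective-point-of-measurement shift (cm, default 0).
#' @return Effective depth in cm.
#' @examples
#' effective_depth(4.1)  # 5.0
#' @export
effective_depth <- function(slab_thickness, inherent_buildup = 0.9,
                            epom_shift = 0) {
  vals <- c(slab_thickness, inherent_buildup, epom_shift)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_compscan("all depth components must be >= 0 (cm)",
                  "invalid_parameter")
  }
  slab_thickness + inherent_buildup + epom_shift
}
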