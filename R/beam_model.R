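#' Parametric description of a photon beam profile
#'
#' A `beam_spec` collects everything the analytic beam model needs to generate
#' a continuous relative-dose profile at a measurement plane: the nominal
#' square field width defined at the isocenter plane, the geometry
#' (SSD, depth, source-axis distance), and the shape parameters of the model
#' (penumbra edge-spread scale, out-of-field scatter tail, in-field horns, and
#' an optional wedge gradient).
#'
#' The energy label is metadata only: 6 MV vs 23 MV beams are expressed
#' through the shape parameters the user chooses, not hard-coded physics.
#'
#' @param field_width_iso Nominal square field side at the isocenter plane
#'   (cm, at `source_axis_distance` from the source). Must be positive.
#' @param ssd Source-to-surface distance (cm, > 0).
#' @param depth Measurement depth below the surface (cm, >= 0).
#' @param energy_label Free-text energy tag, e.g. `"6MV"` or `"23MV"`.
#' @param penumbra_sigma Edge-spread scale of the error-function penumbra
#'   (cm, > 0).
#' @param tail_fraction Out-of-field scatter floor as a fraction of the
#'   central-axis dose, in `[0, 0.2]`.
#' @param tail_decay Exponential decay rate of the scatter tail beyond the
#'   field edge (1/cm, > 0).
#' @param horn_amplitude Relative amplitude of the quadratic in-field horns,
#'   in `[-0.1, 0.1]`. Zero gives a flat top.
#' @param wedge_gradient Exponential wedge gradient (1/cm); 0 for an open
#'   field.
#' @param source_axis_distance Source-axis distance at which
#'   `field_width_iso` is defined (cm, default 100).
#'
#' @return An object of class `beam_spec`.
#' @examples
#' spec <- beam_spec(field_width_iso = 10, ssd = 100, depth = 5)
#' open_profile(spec, c(-6, 0, 6))
#' @export
beam_spec <- function(field_width_iso,
                      ssd = 100,
                      depth = 5,
                      energy_label = "6MV",
                      penumbra_sigma = 0.3,
                      tail_fraction = 0.03,
                      tail_decay = 0.5,
                      horn_amplitude = 0,
                      wedge_gradient = 0,
                      source_axis_distance = 100) {
  if (!is.numeric(field_width_iso) || length(field_width_iso) != 1L ||
      !is.finite(field_width_iso) || field_width_iso <= 0) {
    stop_compscan("'field_width_iso' must be a single positive number (cm)",
                  "invalid_parameter")
  }
  if (!is.numeric(ssd) || length(ssd) != 1L || !is.finite(ssd) || ssd <= 0) {
    stop_compscan("'ssd' must be a single positive number (cm)",
                  "invalid_parameter")
  }
  if (!is.numeric(depth) || length(depth) != 1L || !is.finite(depth) ||
      depth < 0) {
    stop_compscan("'depth' must be a single non-negative number (cm)",
                  "invalid_parameter")
  }
  if (!is.finite(penumbra_sigma) || penumbra_sigma <= 0) {
    stop_compscan("'penumbra_sigma' must be > 0 (cm)", "invalid_parameter")
  }
  if (!is.finite(tail_fraction) || tail_fraction < 0 || tail_fraction > 0.2) {
    stop_compscan("'tail_fraction' must lie in [0, 0.2]", "invalid_parameter")
  }
  if (!is.finite(tail_decay) || tail_decay <= 0) {
    stop_compscan("'tail_decay' must be > 0 (1/cm)", "invalid_parameter")
  }
  if (!is.finite(horn_amplitude) || abs(horn_amplitude) > 0.1) {
    stop_compscan("'horn_amplitude' must lie in [-0.1, 0.1]",
                  "invalid_parameter")
  }
  if (!is.finite(wedge_gradient)) {
    stop_compscan("'wedge_gradient' must be finite (1/cm)",
                  "invalid_parameter")
  }
  if (!is.finite(source_axis_distance) || source_axis_distance <= 0) {
    stop_compscan("'source_axis_distance' must be > 0 (cm)",
                  "invalid_parameter")
  }
  structure(
    list(
      field_width_iso = field_width_iso,
      ssd = ssd,
      depth = depth,
      energy_label = as.character(energy_label),
      penumbra_sigma = penumbra_sigma,
      tail_fraction = tail_fraction,
      tail_decay = tail_decay,
      horn_amplitude = horn_amplitude,
      wedge_gradient = wedge_gradient,
      source_axis_distance = source_axis_distance
    ),
    class = "beam_spec"
  )
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf(
    "<beam_spec> %s, %g x %g cm field (iso), SSD %g cm, depth %g cm\n",
    x$energy_label, x$field_width_iso, x$field_width_iso, x$ssd, x$depth))
  cat(sprintf(
    "  penumbra sigma %g cm, tail %g (decay %g /cm), horns %g, wedge %g /cm\n",
    x$penumbra_sigma, x$tail_fraction, x$tail_decay, x$horn_amplitude,
    x$wedge_gradient))
  invisible(x)
}

#' Project a nominal field size onto the measurement plane
#'
#' Scales a square field side defined at the isocenter plane to the
#' measurement plane at `ssd + depth` from the source by beam divergence:
#' `field_width_iso * (ssd + depth) / sad`. A 40 cm field at 70 cm SSD and
#' zero depth projects to 28 cm, which is how a 40 x 40 cm field is brought
#' within a 32 cm array span.
#'
#' @param field_width_iso Field side at the isocenter plane (cm, > 0).
#' @param ssd Source-to-surface distance (cm, > 0).
#' @param depth Depth of the measurement plane below the surface (cm, >= 0).
#' @param sad Distance from source at which the nominal field is defined
#'   (cm, default 100).
#' @return The field side length (cm) at the measurement plane.
#' @examples
#' project_field_size(40, 70, 0)  # 28
#' project_field_size(40, 70, 5)  # 30
#' @export
project_field_size <- function(field_width_iso, ssd, depth = 0, sad = 100) {
  if (!is.finite(field_width_iso) || field_width_iso <= 0) {
    stop_compscan("'field_width_iso' must be > 0", "invalid_parameter")
  }
  if (!is.finite(ssd) || ssd <= 0) {
    stop_compscan("'ssd' must be > 0", "invalid_parameter")
  }
  if (!is.finite(depth) || depth < 0) {
    stop_compscan("'depth' must be >= 0", "invalid_parameter")
  }
  if (!is.finite(sad) || sad <= 0) {
    stop_compscan("'sad' must be > 0", "invalid_parameter")
  }
  field_width_iso * (ssd + depth) / sad
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Unnormalized open-field fluence model: double-erf flat top with quadratic
# horns inside the field and an exponential scatter tail outside it.
open_profile_raw <- function(spec, x) {
  h <- project_field_size(spec$field_width_iso, spec$ssd, spec$depth,
                          spec$source_axis_distance) / 2
  s <- spec$penumbra_sigma * sqrt(2)
  flat <- 0.5 * (erf((h - x) / s) + erf((h + x) / s))
  horns <- 1 + spec$horn_amplitude * (pmin(abs(x), h) / h)^2
  tail <- spec$tail_fraction * exp(-spec$tail_decay * pmax(0, abs(x) - h))
  flat * horns + tail
}

#' Analytic open-field beam profile
#'
#' Evaluates the continuous ground-truth relative-dose profile at the
#' measurement plane: an error-function flat top of half-width
#' `project_field_size(...) / 2` with edge scale `penumbra_sigma`, modulated
#' by quadratic horns inside the field, plus an exponentially decaying
#' out-of-field scatter tail. The result is normalized so the central-axis
#' (x = 0) dose is exactly 100.
#'
#' @param spec A [beam_spec()].
#' @param positions Positions (cm) in the fixed beam frame at the measurement
#'   plane; must be finite.
#' @return Relative dose values (CAX = 100), one per position.
#' @examples
#' spec <- beam_spec(field_width_iso = 10)
#' open_profile(spec, 0)                 # exactly 100
#' open_profile(spec, c(-5.25, 5.25))    # symmetric penumbra
#' @export
open_profile <- function(spec, positions) {
  stopifnot(inherits(spec, "beam_spec"))
  if (!is.numeric(positions) || any(!is.finite(positions))) {
    stop_compscan("'positions' must be finite numbers (cm)",
                  "invalid_parameter")
  }
  100 * open_profile_raw(spec, positions) / open_profile_raw(spec, 0)
}

#' Analytic wedged beam profile
#'
#' Applies an exponential wedge surrogate `exp(-wedge_gradient * x)` to the
#' open-field model and renormalizes so the central-axis dose is 100. For a
#' positive gradient the profile is strictly monotone decreasing across the
#' in-field region, which is the property the dynamic-wedge comparison
#' machinery needs; the surrogate does not model jaw-motion physics.
#'
#' @inheritParams open_profile
#' @return Relative dose values (CAX = 100), one per position.
#' @examples
#' spec <- beam_spec(field_width_iso = 10, wedge_gradient = 0.06)
#' wedge_profile(spec, c(-3, 0, 3))
#' @export
wedge_profile <- function(spec, positions) {
  stopifnot(inherits(spec, "beam_spec"))
  if (spec$wedge_gradient == 0) {
    stop_compscan(
      "'wedge_gradient' is 0; use open_profile() for open fields",
      "invalid_parameter")
  }
  if (!is.numeric(positions) || any(!is.finite(positions))) {
    stop_compscan("'positions' must be finite numbers (cm)",
                  "invalid_parameter")
  }
  raw <- open_profile_raw(spec, positions) *
    exp(-spec$wedge_gradient * positions)
  100 * raw / open_profile_raw(spec, 0)
}

#' Continuous dose function for a beam specification
#'
#' Returns a vectorized function `f(x)` evaluating the analytic profile
#' (wedged if `wedge_gradient != 0`, open otherwise) in relative dose with
#' CAX = 100. This is the form the virtual array sampler consumes.
#'
#' @inheritParams open_profile
#' @return A function of one numeric vector argument (positions in cm).
#' @export
beam_profile_fun <- function(spec) {
  stopifnot(inherits(spec, "beam_spec"))
  if (spec$wedge_gradient != 0) {
    function(x) wedge_profile(spec, x)
  } else {
    function(x) open_profile(spec, x)
  }
}
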