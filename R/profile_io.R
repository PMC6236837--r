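#' @name profile_file
#' @title Columnar text format for profile scans
#'
#' @description
#' Profile scans are stored as UTF-8 text: header lines beginning `#` carry
#' `key=value` metadata (`axis`, `field_width_iso_cm`, `ssd_cm`, `depth_cm`,
#' `energy`, `normalization`, `composite_spacing_cm`, plus any user keys,
#' which are preserved on a round trip), followed by body rows
#' `position_cm<TAB>dose_rel` with positions ascending. Numbers are written
#' with 17 significant digits so `read_profile(write_profile(x))` restores
#' `x` bit-exactly.
NULL

numeric_meta_keys <- c("field_width_iso_cm", "ssd_cm", "depth_cm",
                       "composite_spacing_cm")

# %.17g round-trips IEEE doubles exactly and strips trailing zeros
fmt_num <- function(x) sprintf("%.17g", x)

#' Write a profile scan to a columnar text file
#'
#' @param scan A [profile_scan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [profile_file] for the format.
#' @export
write_profile <- function(scan, path) {
  stopifnot(inherits(scan, "profile_scan"))
  header <- c(sprintf("# axis=%s", scan$axis_label))
  for (key in names(scan$meta)) {
    val <- scan$meta[[key]]
    val <- if (is.numeric(val)) fmt_num(val) else as.character(val)
    header <- c(header, sprintf("# %s=%s", key, val))
  }
  body <- paste(fmt_num(scan$positions), fmt_num(scan$doses), sep = "\t")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

parse_headers <- function(lines) {
  hdr <- sub("^#\\s*", "", lines)
  kv <- regmatches(hdr, regexpr("=", hdr), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "",
                 character(1))
  stats::setNames(as.list(vals), trimws(keys))
}

#' Read a profile scan from a columnar text file
#'
#' @param path Input file path in the [profile_file] format.
#' @return A [profile_scan()].
#' @export
read_profile <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_hdr <- grepl("^#", lines)
  meta <- parse_headers(lines[is_hdr])
  axis <- meta[["axis"]]
  if (is.null(axis)) {
    axis <- "X-crossline"
  }
  meta[["axis"]] <- NULL
  for (key in intersect(names(meta), numeric_meta_keys)) {
    meta[[key]] <- as.numeric(meta[[key]])
  }
  body <- lines[!is_hdr & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  positions <- as.numeric(vapply(parts, `[`, character(1), 1L))
  doses <- as.numeric(vapply(parts, `[`, character(1), 2L))
  profile_scan(positions, doses, axis_label = axis, meta = meta)
}

#' Write an array acquisition to a text file
#'
#' One text block per acquisition: `#` header lines with the couch state,
#' MU, axis, geometry and seed, then `index<TAB>reading` rows.
#'
#' @param acq An [acquire()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_acquisition <- function(acq, path) {
  stopifnot(inherits(acq, "array_acquisition"))
  g <- acq$geometry
  header <- c(
    sprintf("# axis=%s", g$axis_label),
    sprintf("# pitch_cm=%s", fmt_num(g$pitch)),
    sprintf("# index_min=%d", g$index_range[1]),
    sprintf("# index_max=%d", g$index_range[2]),
    sprintf("# central_index=%d", g$central_index),
    sprintf("# missing_indices=%s",
            paste(g$missing_indices, collapse = ",")),
    sprintf("# chamber_width_cm=%s", fmt_num(g$chamber_width)),
    sprintf("# couch_x_cm=%s", fmt_num(acq$couch$x_shift)),
    sprintf("# couch_y_cm=%s", fmt_num(acq$couch$y_shift)),
    sprintf("# rotation_deg=%s", fmt_num(acq$couch$rotation_deg)),
    sprintf("# mu=%s", fmt_num(acq$mu)),
    sprintf("# noise_cov=%s", fmt_num(acq$noise_cov)),
    sprintf("# seed=%s", if (is.null(acq$seed)) "" else
      fmt_num(as.numeric(acq$seed)))
  )
  body <- paste(acq$indices, fmt_num(unname(acq$readings)), sep = "\t")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read an array acquisition from a text file
#'
#' @param path Input file path written by [write_acquisition()].
#' @return An `array_acquisition` object.
#' @export
read_acquisition <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_hdr <- grepl("^#", lines)
  h <- parse_headers(lines[is_hdr])
  missing <- h[["missing_indices"]]
  missing <- if (is.null(missing) || !nzchar(missing)) {
    integer()
  } else {
    as.integer(strsplit(missing, ",", fixed = TRUE)[[1]])
  }
  geometry <- array_geometry(
    axis_label = h[["axis"]],
    pitch = as.numeric(h[["pitch_cm"]]),
    index_range = c(as.integer(h[["index_min"]]),
                    as.integer(h[["index_max"]])),
    central_index = as.integer(h[["central_index"]]),
    missing_indices = missing,
    chamber_width = as.numeric(h[["chamber_width_cm"]])
  )
  couch <- couch_state(
    x_shift = as.numeric(h[["couch_x_cm"]]),
    y_shift = as.numeric(h[["couch_y_cm"]]),
    rotation_deg = as.numeric(h[["rotation_deg"]])
  )
  body <- lines[!is_hdr & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  indices <- as.integer(vapply(parts, `[`, character(1), 1L))
  readings <- as.numeric(vapply(parts, `[`, character(1), 2L))
  seed <- h[["seed"]]
  seed <- if (is.null(seed) || !nzchar(seed)) NULL else as.integer(seed)
  structure(
    list(
      indices = indices,
      readings = stats::setNames(readings, indices),
      couch = couch,
      geometry = geometry,
      mu = as.numeric(h[["mu"]]),
      noise_cov = as.numeric(h[["noise_cov"]]),
      seed = seed
    ),
    class = "array_acquisition"
  )
}
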