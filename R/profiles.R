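#' Beam profile container
#'
#' An ordered half-profile scan: unsigned off-axis coordinate x (cm, from
#' the central axis within one half of the field) and a reading or
#' relative dose value per point. Metadata record which setup produced it,
#' the chamber, the geometry, and whether the values are normalized.
#'
#' @param x Off-axis positions, cm, strictly increasing (x = 0 allowed as
#'   the central-axis point).
#' @param value Readings (electrometer units) or normalized values (%).
#' @param setup \code{"moving_detector"} or \code{"moving_gantry"} — for a
#'   transformed gantry scan this is \code{"moving_detector"} (classical
#'   equivalent).
#' @param geom A \code{\link{beam_geometry}} or NULL.
#' @param chamber \code{"thimble"}, \code{"markus"} or \code{"unknown"}.
#' @param normalized Logical; TRUE when values are percent of a reference.
#' @param half Which half of the field, \code{"upper"} or \code{"lower"}.
#' @return An object of class \code{"beam_profile"} with a \code{data}
#'   data frame (\code{x}, \code{value}) and the metadata fields.
#' @export
beam_profile <- function(x, value,
                         setup = c("moving_detector", "moving_gantry"),
                         geom = NULL,
                         chamber = c("thimble", "markus", "unknown"),
                         normalized = FALSE,
                         half = "upper") {
  setup <- match.arg(setup)
  chamber <- match.arg(chamber)
  stopifnot(is.numeric(x), is.numeric(value), length(x) == length(value))
  if (any(!is.finite(x)) || any(!is.finite(value)))
    stop("profile coordinates and values must be finite")
  if (is.unsorted(x, strictly = TRUE))
    stop("profile x coordinates must be strictly increasing")
  if (any(x < 0)) stop("x is an unsigned half-profile coordinate; use 'half' for the side")
  structure(list(data = data.frame(x = x, value = value),
                 setup = setup, geom = geom, chamber = chamber,
                 normalized = normalized, half = half),
            class = "beam_profile")
}

#' @export
print.beam_profile <- function(x, ...) {
  cat(sprintf("Beam half-profile (%s, %s chamber, %s half): %d points, x in [%g, %g] cm\n",
              x$setup, x$chamber, x$half, nrow(x$data),
              min(x$data$x), max(x$data$x)))
  if (x$normalized) cat("  values normalized (% of reference)\n")
  print(utils::head(x$data, 5))
  if (nrow(x$data) > 5) cat(sprintf("  ... %d more points\n", nrow(x$data) - 5))
  invisible(x)
}

#' @export
as.data.frame.beam_profile <- function(x, ...) x$data

#' Average positive- and negative-polarity readings
#'
#' Spurious cable and polarity signal components are antisymmetric
#' between the two chamber polarities; averaging the magnitudes of the
#' readings taken at positive and negative polarity cancels any such
#' offset exactly.
#'
#' @param reading_plus Reading(s) at positive polarity.
#' @param reading_minus Reading(s) at negative polarity.
#' @return The arithmetic mean of the reading magnitudes.
#' @examples
#' average_polarity(10.02, 9.98)  # 10
#' @export
average_polarity <- function(reading_plus, reading_minus) {
  stopifnot(is.numeric(reading_plus), is.numeric(reading_minus),
            length(reading_plus) == length(reading_minus))
  if (any(!is.finite(reading_plus)) || any(!is.finite(reading_minus)))
    stop("polarity readings must be finite")
  avg <- (abs(reading_plus) + abs(reading_minus)) / 2
  if (any(avg <= 0)) stop("averaged reading magnitude must be positive")
  avg
}

#' Transform a moving-gantry scan into a classical-equivalent profile
#'
#' The core of the moving-gantry method: each reading taken at gantry
#' rotation beta is mapped to the off-axis position x of its ray line and
#' corrected through the inverse-square and directional-response chain, so
#' that the output is directly comparable with (and interchangeable for) a
#' classical moving-detector scan along the same ray lines.
#'
#' @param scan A data frame with column \code{beta} (degrees, strictly
#'   increasing) and either \code{reading} or the polarity pair
#'   \code{reading_plus}/\code{reading_minus} (averaged first).
#' @param geom A \code{\link{beam_geometry}}.
#' @param model A \code{\link{directional_response_model}}.
#' @param mode Correction mode, see \code{\link{correct_reading}}.
#' @param chamber Chamber label stored on the result.
#' @return A \code{\link{beam_profile}} with \code{setup =
#'   "moving_detector"} and the same number of points, plus an attached
#'   \code{breakdown} data frame of per-point correction factors.
#' @export
transform_gantry_profile <- function(scan, geom, model,
                                     mode = c("thimble_ratio", "markus_per_setup"),
                                     chamber = c("thimble", "markus", "unknown")) {
  mode <- match.arg(mode)
  chamber <- match.arg(chamber)
  stopifnot(is.data.frame(scan), "beta" %in% names(scan))
  if (is.unsorted(scan$beta, strictly = TRUE) && nrow(scan) > 1)
    stop("gantry angles must be strictly increasing")
  reading <- scan_readings(scan)
  res <- correct_reading(reading, scan$beta, geom, model, mode)
  prof <- beam_profile(x = x_from_beta(scan$beta, geom),
                       value = res$corrected,
                       setup = "moving_detector", geom = geom,
                       chamber = chamber, normalized = FALSE)
  prof$breakdown <- res$breakdown
  prof
}

# Extract the per-point averaged reading from a scan data frame.
scan_readings <- function(scan) {
  if (all(c("reading_plus", "reading_minus") %in% names(scan))) {
    average_polarity(scan$reading_plus, scan$reading_minus)
  } else if ("reading_plus" %in% names(scan)) {
    warning("only one polarity present; polarity averaging skipped")
    abs(scan$reading_plus)
  } else if ("reading" %in% names(scan)) {
    abs(scan$reading)
  } else {
    stop("scan must contain 'reading' or 'reading_plus'/'reading_minus' columns")
  }
}

#' Apply the Markus directional correction to a classical profile
#'
#' In the Markus comparison the combined attenuation-plus-obliquity factor
#' must be divided out of both scans, each at its own incidence angle: the
#' classical moving-detector scan sees the ray at angle alpha on the
#' vertical phantom face.
#'
#' @param profile A non-normalized classical \code{\link{beam_profile}}
#'   with a geometry attached.
#' @param model An enhancing-form \code{\link{directional_response_model}}.
#' @return The profile with values multiplied by
#'   \code{\link{catt_obl_markus}} at each point's ray angle.
#' @export
apply_markus_correction <- function(profile, model) {
  stopifnot(inherits(profile, "beam_profile"))
  if (is.null(profile$geom)) stop("profile carries no geometry")
  if (profile$normalized) stop("apply the correction before normalization")
  alpha <- rad2deg(atan2(profile$data$x, profile$geom$scd))
  profile$data$value <- profile$data$value * catt_obl_markus(model, alpha)
  profile
}

#' Normalize a profile to a reference value
#'
#' @param profile A \code{\link{beam_profile}}.
#' @param reference \code{"central_axis"} (value at x = 0; default, the
#'   package's convention for half profiles) or \code{"maximum"}.
#' @return The profile rescaled so the reference equals 100 (%).
#'   Idempotent: normalizing twice changes nothing.
#' @export
normalize_profile <- function(profile, reference = c("central_axis", "maximum")) {
  stopifnot(inherits(profile, "beam_profile"))
  reference <- match.arg(reference)
  ref <- if (reference == "central_axis") {
    i <- which(profile$data$x == 0)
    if (length(i) != 1L)
      stop("no central-axis (x = 0) point present; cannot normalize to central_axis")
    profile$data$value[i]
  } else {
    max(profile$data$value)
  }
  if (!is.finite(ref) || ref <= 0) stop("normalization reference must be positive")
  profile$data$value <- profile$data$value / ref * 100
  profile$normalized <- TRUE
  profile
}

#' Interpolate a profile at arbitrary off-axis positions
#'
#' Piecewise-linear interpolation between grid points. Extrapolation is
#' refused: positions outside the scanned range are an error.
#'
#' @param profile A \code{\link{beam_profile}}.
#' @param x Positions, cm, all within the profile's x range.
#' @return Interpolated values at \code{x}.
#' @export
interpolate_profile <- function(profile, x) {
  stopifnot(inherits(profile, "beam_profile"), is.numeric(x))
  rng <- range(profile$data$x)
  if (any(x < rng[1] | x > rng[2]))
    stop(sprintf("position outside the scanned range [%g, %g] cm; no extrapolation",
                 rng[1], rng[2]))
  stats::approx(profile$data$x, profile$data$value, xout = x,
                method = "linear", ties = "ordered")$y
}

#' Position of the 50% profile point
#'
#' Locates the penumbra by the x coordinate at which a normalized profile
#' crosses 50% of its reference value, by linear interpolation between the
#' bracketing grid points. The profile must cross 50% exactly once in
#' monotone descent; no crossing or multiple crossings are errors.
#'
#' @param profile A normalized \code{\link{beam_profile}}.
#' @param level Crossing level in percent (default 50).
#' @return The crossing position in cm.
#' @export
half_value_position <- function(profile, level = 50) {
  stopifnot(inherits(profile, "beam_profile"))
  if (!profile$normalized)
    stop("profile must be normalized before locating the 50% point")
  v <- profile$data$value
  x <- profile$data$x
  above <- v >= level
  # indices i where the profile passes from >= level to < level
  cross <- which(above[-length(above)] & !above[-1])
  if (length(cross) == 0L)
    stop(sprintf("profile never descends through %g%%", level))
  if (length(cross) > 1L)
    stop(sprintf("profile crosses %g%% more than once (near x = %s cm)",
                 level, paste(signif(x[cross], 4), collapse = ", ")))
  i <- cross
  x[i] + (level - v[i]) * (x[i + 1] - x[i]) / (v[i + 1] - v[i])
}

#' Compare two normalized profiles point by point
#'
#' Differences are evaluated on the first profile's grid, with the second
#' profile linearly interpolated, and expressed in percentage points of
#' the normalization (central-axis) value — a fixed scale, so a stated
#' agreement like "better than 0.5%" means the same thing in the flat core
#' and deep in the penumbra.
#'
#' @param p1,p2 Normalized \code{\link{beam_profile}}s with overlapping
#'   x ranges.
#' @return A list of class \code{"profile_comparison"}: \code{table}
#'   (x, value1, value2, diff), \code{max_abs_diff}, \code{x_range}, and
#'   \code{halfpoint_offset} (difference of the 50% positions, cm, or NA
#'   when either profile has no penumbra crossing in the overlap).
#' @export
compare_profiles <- function(p1, p2) {
  stopifnot(inherits(p1, "beam_profile"), inherits(p2, "beam_profile"))
  if (!p1$normalized || !p2$normalized)
    stop("both profiles must be normalized before comparison")
  lo <- max(min(p1$data$x), min(p2$data$x))
  hi <- min(max(p1$data$x), max(p2$data$x))
  if (lo > hi) stop("profiles have no overlapping x range")
  keep <- p1$data$x >= lo & p1$data$x <= hi
  x <- p1$data$x[keep]
  v1 <- p1$data$value[keep]
  v2 <- interpolate_profile(p2, x)
  diff <- v1 - v2
  hv1 <- tryCatch(half_value_position(p1), error = function(e) NA_real_)
  hv2 <- tryCatch(half_value_position(p2), error = function(e) NA_real_)
  structure(list(table = data.frame(x = x, value1 = v1, value2 = v2, diff = diff),
                 max_abs_diff = max(abs(diff)),
                 x_range = c(lo, hi),
                 halfpoint_offset = hv1 - hv2),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("Profile comparison over x in [%g, %g] cm (%d points)\n",
              x$x_range[1], x$x_range[2], nrow(x$table)))
  cat(sprintf("  max |difference| : %.4g %% of central-axis value\n", x$max_abs_diff))
  if (is.finite(x$halfpoint_offset))
    cat(sprintf("  50%%-point offset : %.4g cm\n", x$halfpoint_offset))
  invisible(x)
}

#' Project an off-axis distance between measurement planes
#'
#' Similar-triangles scaling from the source: a distance x measured in the
#' plane at \code{from_plane} cm from the source corresponds to
#' \code{x * to_plane / from_plane} in the plane at \code{to_plane} cm.
#'
#' @param x Off-axis distance, cm.
#' @param from_plane,to_plane Source-to-plane distances, cm, > 0.
#' @return The projected distance in cm.
#' @examples
#' project_distance(0.95, 300, 100)  # ~0.32 cm back at isocenter distance
#' @export
project_distance <- function(x, from_plane, to_plane) {
  stopifnot(is.numeric(x), is.numeric(from_plane), is.numeric(to_plane))
  if (any(from_plane <= 0) || any(to_plane <= 0))
    stop("plane distances must be positive")
  x * to_plane / from_plane
}
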