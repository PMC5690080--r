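#' Measurement geometry for extended-SSD profile scans
#'
#' Bundles the three distances that fully describe both the classical
#' (moving detector) and the moving-gantry measurement setup: the
#' source-to-isocenter distance \code{f}, the isocenter-to-phantom-surface
#' distance \code{e}, and the depth \code{d} of the effective point of
#' measurement of the chamber in the phantom. The source-to-detector
#' distance along the central axis is \code{f + e + d}.
#'
#' All angles at the package interface are in degrees; all distances in cm.
#'
#' @param f Source-to-isocenter distance in cm (> 0).
#' @param e Isocenter-to-phantom-surface distance in cm (> 0).
#' @param d Depth of the effective point of measurement in cm (>= 0).
#' @return An object of class \code{"beam_geometry"}: a list with fields
#'   \code{f}, \code{e}, \code{d} and the derived axial source-to-detector
#'   distance \code{scd = f + e + d}.
#' @examples
#' geom <- beam_geometry(f = 100, e = 200, d = 1.2)
#' geom$scd
#' @export
beam_geometry <- function(f = 100, e = 200, d = 1.2) {
  stopifnot(is.numeric(f), is.numeric(e), is.numeric(d),
            length(f) == 1L, length(e) == 1L, length(d) == 1L)
  if (!is.finite(f) || f <= 0) stop("'f' must be a positive finite distance (cm)")
  if (!is.finite(e) || e <= 0) stop("'e' must be a positive finite distance (cm)")
  if (!is.finite(d) || d < 0)  stop("'d' must be a nonnegative finite depth (cm)")
  structure(list(f = f, e = e, d = d, scd = f + e + d),
            class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat("Extended-SSD measurement geometry\n")
  cat(sprintf("  f (source-isocenter)    : %g cm\n", x$f))
  cat(sprintf("  e (isocenter-surface)   : %g cm\n", x$e))
  cat(sprintf("  d (measurement depth)   : %g cm\n", x$d))
  cat(sprintf("  f+e+d (axial SCD)       : %g cm\n", x$scd))
  invisible(x)
}

#' Default geometry presets
#'
#' The standard commissioning setup: 100 cm source-to-isocenter, phantom
#' surface at 300 cm from the source, chamber effective point at the depth
#' of dose maximum (1.2 cm, thimble chamber) or at 0.2 cm (Markus chamber).
#'
#' @param chamber One of \code{"thimble"} (d = 1.2 cm) or
#'   \code{"markus"} (d = 0.2 cm).
#' @return A \code{\link{beam_geometry}}.
#' @export
default_geometry <- function(chamber = c("thimble", "markus")) {
  chamber <- match.arg(chamber)
  beam_geometry(f = 100, e = 200, d = if (chamber == "thimble") 1.2 else 0.2)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

check_beta <- function(beta) {
  if (!is.numeric(beta) || any(!is.finite(beta)))
    stop("gantry rotation 'beta' must be finite numeric degrees")
  if (any(beta < 0 | beta >= 90))
    stop("gantry rotation 'beta' must lie in [0, 90) degrees: ",
         "the formalism is derived for the upper-half scan")
  invisible(beta)
}

#' Ray angle to the central axis from the gantry rotation
#'
#' For a detector fixed on the central axis at \code{f + e + d} from the
#' source base position, rotating the gantry by \code{beta} degrees sends
#' through the detector the ray line that, in the classical setup, makes
#' the angle \eqn{\alpha = \beta - \arctan\!\big(f \sin\beta / (f \cos\beta
#' + e + d)\big)} with the central axis.
#'
#' @param beta Gantry rotation from the horizontal central axis, degrees,
#'   vectorized, each in \code{[0, 90)}.
#' @param geom A \code{\link{beam_geometry}}.
#' @return Ray angle \eqn{\alpha} in degrees (same length as \code{beta});
#'   strictly increasing in \code{beta}, with \code{alpha_from_beta(0) == 0}.
#' @seealso \code{\link{incidence_angle}}, \code{\link{x_from_beta}}
#' @examples
#' alpha_from_beta(20, beam_geometry(100, 200, 1.2))
#' @export
alpha_from_beta <- function(beta, geom) {
  stopifnot(inherits(geom, "beam_geometry"))
  check_beta(beta)
  b <- deg2rad(beta)
  beta - rad2deg(atan2(geom$f * sin(b), geom$f * cos(b) + geom$e + geom$d))
}

#' Incidence angle onto the phantom surface in the moving-gantry setup
#'
#' With the phantom face vertical and fixed on the central axis, the ray
#' selected by gantry rotation \code{beta} strikes the surface at
#' \eqn{\phi = \beta - \alpha} degrees from the surface normal. This is
#' the angle that drives the path length to depth \code{d} and the
#' chamber's directional response.
#'
#' @inheritParams alpha_from_beta
#' @return Incidence angle \eqn{\phi} in degrees; nonnegative and strictly
#'   increasing in \code{beta}.
#' @examples
#' # the gantry swings 20 degrees but the ray tilts only ~6.6 degrees:
#' incidence_angle(20, beam_geometry(100, 200, 0.2))
#' @export
incidence_angle <- function(beta, geom) {
  beta - alpha_from_beta(beta, geom)
}

#' Off-axis position equivalent to a gantry rotation
#'
#' Maps the gantry rotation \code{beta} to the off-axis distance
#' \eqn{x = (f+e+d)\,\tan\alpha} at which the classical moving-detector
#' scan samples the same ray line in the vertical measurement plane.
#'
#' @inheritParams alpha_from_beta
#' @return Off-axis distance x in cm; strictly increasing in \code{beta},
#'   with \code{x_from_beta(0) == 0}.
#' @examples
#' x_from_beta(20, beam_geometry(100, 200, 1.2))  # outermost scan point
#' @export
x_from_beta <- function(beta, geom) {
  geom$scd * tan(deg2rad(alpha_from_beta(beta, geom)))
}

#' Gantry rotation reaching a given off-axis position
#'
#' Numerical inverse of \code{\link{x_from_beta}}. The forward map is
#' strictly increasing on \code{[0, 90)} degrees, so the root is unique;
#' it is located with Brent's method on the bracket \code{[0, 89.9]}.
#'
#' @param x Off-axis distance in cm (>= 0), vectorized.
#' @param geom A \code{\link{beam_geometry}}.
#' @param tol Convergence tolerance on beta, degrees.
#' @return Gantry rotation beta in degrees with
#'   \code{x_from_beta(beta, geom)} equal to \code{x} within tolerance.
#' @export
beta_from_x <- function(x, geom, tol = 1e-10) {
  stopifnot(inherits(geom, "beam_geometry"))
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric cm")
  if (any(x < 0)) stop("'x' must be nonnegative (unsigned half-profile coordinate)")
  vapply(x, function(xi) {
    if (xi == 0) return(0)
    upper <- 89.9
    if (x_from_beta(upper, geom) < xi)
      stop(sprintf("x = %g cm is beyond the reach of the scan (no beta in [0, 89.9])", xi))
    stats::uniroot(function(b) x_from_beta(b, geom) - xi,
                   interval = c(0, upper), tol = tol)$root
  }, numeric(1))
}

#' Inverse-square correction factor between the two setups
#'
#' The moving-gantry setup places the source closer to the detector than
#' the classical setup does along the same ray line. The reading taken at
#' gantry rotation \code{beta} must therefore be scaled by
#' \eqn{C_{isq} = (F'_M / F''_M)^2}, where
#' \eqn{F'_M = \sqrt{(f\cos\beta + e + d)^2 + f^2\sin^2\beta}} is the
#' gantry-setup source-to-detector distance and
#' \eqn{F''_M = (f+e+d)/\cos\alpha} the classical one.
#'
#' @inheritParams alpha_from_beta
#' @return Dimensionless factor, equal to 1 at \code{beta = 0} and
#'   decreasing as the gantry swings away from the horizontal.
#' @examples
#' inverse_square_factor(20, beam_geometry(100, 200, 1.2))  # ~0.921
#' @export
inverse_square_factor <- function(beta, geom) {
  stopifnot(inherits(geom, "beam_geometry"))
  check_beta(beta)
  b <- deg2rad(beta)
  a <- deg2rad(alpha_from_beta(beta, geom))
  f_gantry    <- sqrt((geom$f * cos(b) + geom$e + geom$d)^2 + (geom$f * sin(b))^2)
  f_classical <- geom$scd / cos(a)
  (f_gantry / f_classical)^2
}

#' Projected step width of a gantry increment
#'
#' The off-axis distance swept in the measurement plane when the gantry
#' advances from \code{beta} to \code{beta + dbeta}. A 0.1 degree
#' increment corresponds to roughly 0.35 cm on axis and 0.37 cm at 20
#' degrees for the 300 cm setup.
#'
#' @param beta Starting gantry rotation, degrees.
#' @param dbeta Gantry increment, degrees (\code{beta + dbeta} must stay
#'   in the domain).
#' @param geom A \code{\link{beam_geometry}}.
#' @return Step width in cm.
#' @export
step_width <- function(beta, dbeta, geom) {
  x_from_beta(beta + dbeta, geom) - x_from_beta(beta, geom)
}

#' Full ray-line mapping for a set of gantry rotations
#'
#' Tabulates, for each gantry rotation beta, the equivalent classical ray
#' angle alpha, the surface incidence angle phi = beta - alpha, and the
#' off-axis position x, together with the inverse-square factor.
#'
#' @inheritParams alpha_from_beta
#' @return A data frame with columns \code{beta}, \code{alpha},
#'   \code{phi} (degrees), \code{x} (cm) and \code{c_isq}.
#' @examples
#' ray_mapping(c(0, 10, 20), beam_geometry(100, 200, 1.2))
#' @export
ray_mapping <- function(beta, geom) {
  alpha <- alpha_from_beta(beta, geom)
  data.frame(beta = beta,
             alpha = alpha,
             phi = beta - alpha,
             x = x_from_beta(beta, geom),
             c_isq = inverse_square_factor(beta, geom))
}
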