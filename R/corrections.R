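#' Chamber directional-response model
#'
#' Empirical power-law model of an ionization chamber's relative response
#' as a function of the beam incidence angle phi (degrees from the
#' phantom-surface normal), normalized to perpendicular incidence:
#' \itemize{
#'   \item \code{form = "diminishing"}: \eqn{R(\phi)/R(0) = 1 - a\,\phi^b}
#'     (thimble chamber at depth: more oblique rays traverse more phantom
#'     material before the chamber, so the reading drops);
#'   \item \code{form = "enhancing"}: \eqn{R(\phi)/R(0) = 1 + a\,\phi^b}
#'     (Markus parallel-plate chamber near the surface: the combined
#'     attenuation-plus-obliquity effect raises the reading).
#' }
#' The model is calibrated over a finite sweep of phantom angles;
#' \code{validity_deg} records that sweep limit and evaluation beyond it
#' warns rather than errors.
#'
#' @param form \code{"diminishing"} or \code{"enhancing"}.
#' @param a Coefficient, per degree^b (>= 0).
#' @param b Exponent, dimensionless (> 0).
#' @param validity_deg Upper limit of the calibrated angular range, degrees.
#' @param ssd_label Nominal calibration source-to-surface distance, cm.
#' @param chamber_label Free-text chamber description.
#' @return An object of class \code{"directional_response"}.
#' @seealso \code{\link{response_preset}}, \code{\link{fit_directional_response}}
#' @export
directional_response_model <- function(form = c("diminishing", "enhancing"),
                                       a, b, validity_deg = 30,
                                       ssd_label = NA_real_,
                                       chamber_label = "") {
  form <- match.arg(form)
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (!is.finite(a) || a < 0) stop("coefficient 'a' must be finite and >= 0")
  if (!is.finite(b) || b <= 0) stop("exponent 'b' must be finite and > 0")
  if (form == "diminishing" && a * validity_deg^b >= 1)
    stop("diminishing model would reach zero response inside its validity range")
  structure(list(form = form, a = a, b = b,
                 validity_deg = validity_deg,
                 ssd_label = ssd_label,
                 chamber_label = chamber_label),
            class = "directional_response")
}

#' @export
print.directional_response <- function(x, ...) {
  sign <- if (x$form == "diminishing") "-" else "+"
  cat(sprintf("Directional response model: R(phi)/R(0) = 1 %s %g * phi^%g\n",
              sign, x$a, x$b))
  cat(sprintf("  valid to %g deg", x$validity_deg))
  if (!is.na(x$ssd_label)) cat(sprintf(", calibrated at %g cm SSD", x$ssd_label))
  if (nzchar(x$chamber_label)) cat(sprintf(" (%s)", x$chamber_label))
  cat("\n")
  if (!is.null(x$fit)) {
    cat(sprintf("  fitted to %d points, residual norm %.3g\n",
                x$fit$n, x$fit$residual_norm))
  }
  invisible(x)
}

#' Published directional-response presets
#'
#' Fitted power-law constants for the two chambers at their calibration
#' distances:
#' \describe{
#'   \item{\code{"thimble-300"}}{PTW thimble chamber at 1.2 cm depth,
#'     300 cm SSD: \eqn{1 - 0.00018\,\phi^{2.0}}, valid to 20 degrees.}
#'   \item{\code{"markus-100"}}{Markus chamber at 0.2 cm depth, 100 cm
#'     SSD: \eqn{1 + 0.0000114\,\phi^{2.5}}, valid to 30 degrees.}
#'   \item{\code{"markus-300"}}{Markus chamber at 0.2 cm depth, 300 cm
#'     SSD: \eqn{1 + 0.0000325\,\phi^{2.3}}, valid to 30 degrees.}
#' }
#'
#' @param name Preset name.
#' @return A \code{\link{directional_response_model}}.
#' @examples
#' directional_response(response_preset("markus-300"), 6.6)
#' @export
response_preset <- function(name = c("thimble-300", "markus-100", "markus-300")) {
  name <- match.arg(name)
  switch(name,
    "thimble-300" = directional_response_model(
      "diminishing", a = 0.00018, b = 2.0, validity_deg = 20,
      ssd_label = 300, chamber_label = "thimble"),
    "markus-100" = directional_response_model(
      "enhancing", a = 0.0000114, b = 2.5, validity_deg = 30,
      ssd_label = 100, chamber_label = "markus"),
    "markus-300" = directional_response_model(
      "enhancing", a = 0.0000325, b = 2.3, validity_deg = 30,
      ssd_label = 300, chamber_label = "markus"))
}

#' Evaluate a directional-response model
#'
#' @param model A \code{\link{directional_response_model}}.
#' @param phi Incidence angle(s), degrees, >= 0.
#' @return Relative response \eqn{1 \mp a\,\phi^b}; exactly 1 at phi = 0.
#'   Angles beyond the model's validity range are evaluated with a warning
#'   (extrapolated power law).
#' @export
directional_response <- function(model, phi) {
  stopifnot(inherits(model, "directional_response"))
  if (!is.numeric(phi) || any(!is.finite(phi)))
    stop("'phi' must be finite numeric degrees")
  if (any(phi < 0)) stop("'phi' must be nonnegative")
  if (any(phi > model$validity_deg))
    warning(sprintf(
      "incidence angle beyond the %g deg calibration range; power law extrapolated",
      model$validity_deg))
  term <- model$a * phi^model$b
  if (model$form == "diminishing") 1 - term else 1 + term
}

#' Thimble-chamber attenuation correction between the two setups
#'
#' Along one ray line the classical setup presents the chamber with
#' incidence angle alpha while the moving-gantry setup presents phi < alpha.
#' Bringing a gantry reading onto the classical scale therefore requires
#' the ratio of the diminishing directional responses,
#' \eqn{C_{att} = (1 - a\,\alpha^b) / (1 - a\,\phi^b)}.
#' Obliquity proper is taken as 1 for the cylindrically symmetric thimble.
#'
#' @param model A diminishing-form \code{\link{directional_response_model}}.
#' @param alpha Classical-setup ray/incidence angle, degrees.
#' @param phi Moving-gantry incidence angle, degrees.
#' @return Dimensionless correction; 1 when \code{alpha == phi}, < 1 when
#'   \code{alpha > phi}.
#' @export
catt_thimble <- function(model, alpha, phi) {
  stopifnot(inherits(model, "directional_response"))
  if (model$form != "diminishing")
    stop("thimble attenuation correction requires a diminishing-form model")
  den <- directional_response(model, phi)
  if (any(den <= 0)) stop("directional response at phi is non-positive")
  directional_response(model, alpha) / den
}

#' Markus-chamber attenuation-plus-obliquity correction
#'
#' For the parallel-plate Markus chamber the attenuation and obliquity
#' effects cannot be separated empirically; their combined enhancing
#' response \eqn{1 + a\,\phi^b} is divided out of the reading:
#' \eqn{C_{att,obl} = 1 / (1 + a\,\phi^b)}. This correction applies in
#' both setups, each with its own incidence angle (phi for the
#' moving-gantry scan, alpha for the classical scan).
#'
#' @param model An enhancing-form \code{\link{directional_response_model}}.
#' @param phi Incidence angle, degrees.
#' @return Dimensionless correction, <= 1, equal to 1 at phi = 0.
#' @export
catt_obl_markus <- function(model, phi) {
  stopifnot(inherits(model, "directional_response"))
  if (model$form != "enhancing")
    stop("Markus correction requires an enhancing-form model")
  1 / directional_response(model, phi)
}

#' Fit a directional-response power law to calibration readings
#'
#' Calibration data are readings taken with the phantom rotated to a set
#' of incidence angles phi and normalized to the perpendicular reading.
#' The chosen power-law form is fitted by Levenberg-Marquardt nonlinear
#' least squares on the relative readings directly (no log transform:
#' relative responses stay within a few tenths of a percent of 1).
#' Initialization: \code{b = 2}, \code{a} from the largest-angle sample.
#'
#' @param phi Incidence angles, degrees (>= 3 values; should include a
#'   point at or near 0).
#' @param relative_reading Readings normalized to perpendicular incidence
#'   (all > 0).
#' @param form \code{"diminishing"} or \code{"enhancing"}.
#' @param validity_deg Validity limit stored on the returned model;
#'   defaults to the largest calibrated angle.
#' @param ssd_label,chamber_label Metadata passed through to the model.
#' @return A \code{\link{directional_response_model}} with an extra
#'   \code{fit} field (coefficients, residual norm, number of points).
#' @examples
#' phi <- c(0, 5, 10, 15, 20)
#' rel <- 1 - 0.00018 * phi^2
#' fit_directional_response(phi, rel, form = "diminishing")
#' @export
fit_directional_response <- function(phi, relative_reading,
                                     form = c("diminishing", "enhancing"),
                                     validity_deg = NULL,
                                     ssd_label = NA_real_,
                                     chamber_label = "") {
  form <- match.arg(form)
  stopifnot(is.numeric(phi), is.numeric(relative_reading),
            length(phi) == length(relative_reading))
  if (length(phi) < 3L)
    stop("at least 3 calibration samples are required to fit (a, b)")
  if (any(!is.finite(phi)) || any(!is.finite(relative_reading)))
    stop("calibration samples must be finite")
  if (any(relative_reading <= 0))
    stop("relative readings must be positive")
  if (min(phi) > 1)
    warning("no calibration sample near perpendicular incidence (phi = 0)")

  sgn <- if (form == "diminishing") -1 else 1
  # start values: b = 2; a from the deviation of the largest-angle sample
  imax <- which.max(phi)
  dev_max <- sgn * (relative_reading[imax] - 1)
  a0 <- max(dev_max, 1e-8) / max(phi[imax], 1)^2
  dat <- data.frame(phi = phi, rel = relative_reading)
  fit <- tryCatch(
    minpack.lm::nlsLM(rel ~ 1 + sgn * a * phi^b, data = dat,
                      start = list(a = a0, b = 2),
                      lower = c(a = 0, b = 1e-3),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) stop("directional-response fit failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  model <- directional_response_model(
    form, a = unname(cf["a"]), b = unname(cf["b"]),
    validity_deg = if (is.null(validity_deg)) max(phi) else validity_deg,
    ssd_label = ssd_label, chamber_label = chamber_label)
  model$fit <- list(residual_norm = sqrt(sum(stats::resid(fit)^2)),
                    n = length(phi))
  model
}

#' Correct a moving-gantry reading onto the classical scale
#'
#' Applies the full correction chain
#' \eqn{R' = R \cdot C_{isq} \cdot C_{att} \cdot C_{obl}} to a reading
#' taken at gantry rotation \code{beta}:
#' \itemize{
#'   \item \code{mode = "thimble_ratio"}: \eqn{C_{att}} is the ratio of
#'     diminishing responses at alpha and phi
#'     (\code{\link{catt_thimble}}), \eqn{C_{obl} = 1} (cylindrical
#'     symmetry).
#'   \item \code{mode = "markus_per_setup"}: the gantry reading gets the
#'     combined factor \eqn{1/(1 + a\,\phi^b)}
#'     (\code{\link{catt_obl_markus}}) at its own incidence angle phi;
#'     the classical profile being compared against must be corrected
#'     separately at its incidence angle alpha (see
#'     \code{\link{apply_markus_correction}}).
#' }
#'
#' The correction is linear in the reading.
#'
#' @param reading Raw (polarity-averaged) electrometer reading, > 0.
#' @param beta Gantry rotation, degrees.
#' @param geom A \code{\link{beam_geometry}}.
#' @param model A \code{\link{directional_response_model}} matching the mode.
#' @param mode \code{"thimble_ratio"} or \code{"markus_per_setup"}.
#' @return A list with \code{corrected} (the corrected reading) and
#'   \code{breakdown}, a data frame with columns \code{c_isq},
#'   \code{c_att}, \code{c_obl} and \code{combined}.
#' @examples
#' g <- beam_geometry(100, 200, 1.2)
#' correct_reading(1.0, 20, g, response_preset("thimble-300"))
#' @export
correct_reading <- function(reading, beta, geom, model,
                            mode = c("thimble_ratio", "markus_per_setup")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(reading), all(is.finite(reading)))
  if (any(reading <= 0)) stop("readings must be positive")
  if (mode == "thimble_ratio" && model$form != "diminishing")
    stop("thimble_ratio mode requires a diminishing-form response model")
  if (mode == "markus_per_setup" && model$form != "enhancing")
    stop("markus_per_setup mode requires an enhancing-form response model")

  alpha <- alpha_from_beta(beta, geom)
  phi <- beta - alpha
  c_isq <- inverse_square_factor(beta, geom)
  if (mode == "thimble_ratio") {
    c_att <- catt_thimble(model, alpha, phi)
    c_obl <- rep(1, length(c_att))
  } else {
    c_att <- catt_obl_markus(model, phi)
    c_obl <- rep(1, length(c_att))
  }
  combined <- c_isq * c_att * c_obl
  list(corrected = reading * combined,
       breakdown = data.frame(beta = beta, alpha = alpha, phi = phi,
                              c_isq = c_isq, c_att = c_att, c_obl = c_obl,
                              combined = combined))
}
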