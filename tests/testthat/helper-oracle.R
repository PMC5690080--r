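# Independent 2-D coordinate-geometry oracle for the ray-line mapping.
#
# Coordinates: base source at the origin, central axis along +X,
# isocenter at (f, 0), detector fixed at M = (f+e+d, 0). Rotating the
# gantry by beta (upward) moves the source on the radius-f arc about the
# isocenter to S = (f - f*cos(beta), f*sin(beta)), and tilts the beam
# axis to point from S through the isocenter. The oracle derives every
# mapped quantity from these explicit positions and vector angles — no
# use of the package's closed-form expressions.
oracle_ray <- function(beta, f, e, d) {
  b <- beta * pi / 180
  S <- c(f - f * cos(b), f * sin(b))
  M <- c(f + e + d, 0)
  iso <- c(f, 0)
  u <- (iso - S) / sqrt(sum((iso - S)^2))        # rotated beam axis
  v <- (M - S) / sqrt(sum((M - S)^2))            # ray to the detector
  # off-axis angle of the ray within the beam (angle between u and v,
  # via atan2 of cross and dot products — well conditioned at small angles)
  alpha <- atan2(abs(u[1] * v[2] - u[2] * v[1]), sum(u * v)) * 180 / pi
  # incidence on the vertical phantom face: angle between the ray and
  # the +X surface normal
  phi <- atan2(abs(v[2]), v[1]) * 180 / pi
  # classical off-axis position: rotate the ray back about the isocenter
  # (the source returns to the origin, the ray tilts up) and intersect
  # with the plane X = f+e+d
  rot <- matrix(c(cos(b), sin(b), -sin(b), cos(b)), 2, 2)
  vc <- rot %*% v
  x <- (f + e + d) * vc[2] / vc[1]
  # squared distance ratio between the two source-to-detector segments
  f_gantry <- sqrt(sum((M - S)^2))
  f_classical <- sqrt((f + e + d)^2 + x^2)
  list(alpha = alpha, phi = phi, x = as.numeric(x),
       c_isq = (f_gantry / f_classical)^2)
}

oracle_table <- function(betas, f, e, d) {
  rows <- lapply(betas, oracle_ray, f = f, e = e, d = d)
  data.frame(beta = betas,
             alpha = vapply(rows, `[[`, numeric(1), "alpha"),
             phi = vapply(rows, `[[`, numeric(1), "phi"),
             x = vapply(rows, `[[`, numeric(1), "x"),
             c_isq = vapply(rows, `[[`, numeric(1), "c_isq"))
}
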