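---
title: "The moving-gantry method for very large electron-beam profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The moving-gantry method for very large electron-beam profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gantryscan)
```

## The measurement problem

Total skin electron therapy (TSET) irradiates the whole skin surface with
a horizontally directed electron beam at an extended source-to-surface
distance (SSD), typically 300 cm or more, where the uncollimated field
grows to the order of a meter. Commissioning such a beam requires dose
profiles in a vertical plane at treatment distance, preferably at the
depth of maximum dose in a solid phantom. Automated water-phantom
scanners do not reach these distances, so the classical approach moves a
chamber-phantom assembly step by step across the beam on a mechanical
stand — slow, labor-intensive, and limited by the positioning accuracy
of the stand.

The moving-gantry method turns the problem around: the chamber and
phantom stay fixed on the central axis, and the *gantry* rotates in small
angular steps. Each gantry rotation $\beta$ selects a different ray line
of the beam through the fixed detector. Because the accelerator's gantry
angle is set with high reproducibility, the effective spatial sampling is
both fine (a 0.1° step corresponds to about 0.35 cm at 300 cm) and highly
reproducible — but the readings are no longer directly a profile: the
source-to-detector distance and the incidence angle onto the phantom
change with $\beta$, and must be corrected for.

## Geometry: the ray-line mapping

Let $f$ be the source-to-isocenter distance, $e$ the
isocenter-to-phantom-surface distance, and $d$ the depth of the
chamber's effective point of measurement ($f{=}100$, $e{=}200$ cm and
$d{=}1.2$ cm or $0.2$ cm in the reference setup). With the gantry
rotated by $\beta$ from the horizontal, the ray through the fixed
detector makes the angle

$$\alpha \;=\; \beta - \arctan\!\frac{f\sin\beta}{f\cos\beta + e + d}$$

with the central axis of the beam, strikes the vertical phantom face at
incidence $\phi = \beta - \alpha$ from the surface normal, and — in the
classical setup — would be sampled at the off-axis position

$$x \;=\; (f+e+d)\,\tan\alpha .$$

All three relations are implemented from explicit 2-D coordinate
geometry (source on a radius-$f$ arc about the isocenter, detector plane
at $f+e+d$) and are exposed as `alpha_from_beta()`, `incidence_angle()`,
`x_from_beta()` with the numerical inverse `beta_from_x()`. A
consequence worth noting: a 20° gantry swing tilts the ray only about
6.6° off the surface normal — the method samples 70+ cm off axis while
keeping the incidence nearly perpendicular.

```{r}
geom <- beam_geometry(f = 100, e = 200, d = 1.2)
ray_mapping(c(0, 5, 10, 15, 20), geom)
```

Angle unit at every interface is degrees, the unit of the printed
anchors and of linac control; conversion to radians is internal.
`beta_from_x()` uses Brent root finding on the bracket $[0°, 89.9°]$;
strict monotonicity of the forward map guarantees a unique root.

## The correction chain

A gantry-setup reading $R$ is brought onto the classical scale by

$$R' \;=\; R \cdot C_{isq} \cdot C_{att} \cdot C_{obl},$$

with three physically distinct factors:

* **Inverse square** — the gantry setup places the source closer to the
  detector. $C_{isq} = (F'_M/F''_M)^2$ with
  $F'_M = \sqrt{(f\cos\beta+e+d)^2 + f^2\sin^2\beta}$ the gantry-setup
  and $F''_M = (f+e+d)/\cos\alpha$ the classical source-to-detector
  distance along the same ray. It is implemented as this squared
  distance ratio computed from the two source positions, which is the
  unambiguous first-principles form.
* **Attenuation** — the oblique classical ray traverses more phantom
  material to reach depth $d$ than the nearly perpendicular gantry-setup
  ray. For the cylindrically symmetric thimble chamber the empirical
  relative response $R(\phi)/R(0) = 1 - a\phi^{b}$ (fitted constants
  $a=0.00018$, $b=2.0$ at 300 cm SSD) gives
  $C_{att} = (1-a\alpha^{b})/(1-a\phi^{b})$, with $C_{obl}=1$ assumed.
* **Obliquity** — for the parallel-plate Markus chamber attenuation and
  obliquity cannot be separated empirically; the combined enhancing
  response $1 + a\phi^{b}$ ($a=0.0000325$, $b=2.3$ at 300 cm SSD;
  $a=0.0000114$, $b=2.5$ at 100 cm) is divided out of *both* setups,
  each at its own incidence angle: $\phi$ for the gantry scan, $\alpha$
  for the classical scan. In the gantry setup the factor stays within
  0.3% of unity out to $\beta=20°$ — negligible there, decidedly not in
  the classical setup where $\alpha$ reaches 13.4°.

```{r}
correct_reading(1.000, 20, geom, response_preset("thimble-300"))$breakdown
```

The fitted constants ship as presets (`response_preset()`); new
calibration sweeps (readings at a series of phantom angles, normalized
to perpendicular incidence) can be fitted with
`fit_directional_response()`, which runs Levenberg–Marquardt nonlinear
least squares on the power law directly — relative readings sit within
a percent of 1, so a log transform buys nothing — initialized at
$b_0 = 2$ and $a_0$ from the largest-angle sample. Each model records
the angular limit of its calibration sweep (20° thimble, 30° Markus);
evaluation beyond it warns rather than errors, so extrapolation is
possible but never silent.

Readings are averaged over both chamber polarities before correction
(`average_polarity()`): the spurious cable/polarity signal is
antisymmetric between polarities and cancels exactly in the mean, while
the irradiated cable length — held constant by the fixed upper-half scan
geometry — needs no further correction.

## Profiles, comparison conventions

`transform_gantry_profile()` applies the mapping and the correction
chain point by point, turning a gantry scan into a classical-equivalent
profile with the same number of points on a strictly increasing $x$
grid. Downstream conventions, each a deliberate choice:

* **Normalization** is to the central-axis value by default (maximum is
  selectable); half profiles are modeled with an unsigned $x \ge 0$ and
  a labeled half, mirroring how the upper half is actually measured.
* **Comparison** (`compare_profiles()`) evaluates differences on the
  first profile's grid with linear interpolation of the second, in
  *percentage points of the central-axis value* — a fixed scale, so a
  statement like "agreement better than 0.5%" means the same thing in
  the flat core and deep in the penumbra. Matched ray lines are the
  natural grid: the classical scan is designed at the $x$ positions
  computed from the gantry scan's $\beta$ values.
* **Penumbra position** (`half_value_position()`) is the 50% crossing of
  each profile normalized to its own central axis, located by linear
  interpolation; the profile must cross once in monotone descent,
  anything else is an error rather than a silent pick.
* No extrapolation anywhere: interpolation outside the scanned range is
  an error.

`project_distance()` converts off-axis distances between planes by
similar triangles from the source (0.95 cm at 300 cm ↔ 0.32 cm at
100 cm; an 18 cm half-side at the isocenter ↔ the 54 cm half-side of
the 108 cm field at 300 cm).

## The synthetic beam: what it emulates, what it does not

Physical validation data cannot ship with a package, so
`synthetic_beam_model()` provides analytic ground truth: a divergent
point-source field, flat in the core, with an error-function penumbra in
the ray angle $\theta$,

$$\Phi(\theta) = \tfrac12\!\left(1 + \mathrm{erf}\!\frac{\theta_{edge} -
|\theta|}{\sqrt2\,\sigma_\theta}\right),$$

so the 50% fluence level sits exactly at $\theta_{edge}$. Simulated
readings in either setup multiply fluence by the true inverse-square
factor of that setup's source-to-detector distance and the chamber's
directional response at that setup's incidence angle, then split into a
polarity pair with an optional antisymmetric cable offset and
multiplicative Gaussian noise. The two polarity readings are separate
electrometer acquisitions and receive independent noise draws, so a
polarity-averaged point has standard deviation $\sigma/\sqrt2$.

Defaults, fixed once: $\theta_{edge} = \arctan(18/100) \approx 10.2°$
(the 36 cm isocenter field, 108 cm at 300 cm; the 45 cm field preset
scales this to $\arctan(7.5/100)$); $\sigma_\theta = 1.5°$, giving an
80–20 penumbra of roughly 13 cm in the 300 cm plane, typical of an
uncollimated electron field at extended distance; noise and cable
offset off. Scan designs mirror the reference campaign: $\beta = 0°$ to
$20°$ in 1° steps, classical $x$ at the matched ray-line positions.

By construction the simulator's chamber behavior uses exactly the
power-law response forms that the correction chain divides out. That is
deliberate: it separates "does the plumbing invert the setup difference"
(a sharp round-trip identity, testable to machine precision) from "how
wrong is the empirical response model" (probed separately by the
`"mu_exp"` mode, an independent path-length attenuation
$\exp(-\mu d\,(1/\cos\phi - 1))$ that the power-law correction does
*not* exactly invert). What the simulator does **not** emulate: electron
scatter and energy loss in air and phantom, the beam's energy spectrum,
floor scatter, beam-on drift. Passing round-trip tests therefore
demonstrates the correctness of the transform and correction
implementation — not the physical adequacy of the empirical correction
model, which in practice is established by the calibration sweep for
each chamber, depth and SSD.

```{r}
rt <- round_trip_discrepancy(geom)
rt$max_discrepancy_percent     # machine precision: exact inverse
rt_noisy <- round_trip_discrepancy(geom, noise_sigma = 0.002, seed = 1)
rt_noisy$max_discrepancy_percent
```

The noisy figure above is the package's operational mirror of the
reference campaign's "better than 0.5% over the whole measuring range":
with 0.2% per-reading noise on the gantry scan, the corrected readings
land within 0.5% of the noise-free classical truth (as a percentage of
the central-axis reading) in the overwhelming majority of seeds. The
discrepancy is measured on raw corrected readings against the
noise-free reference — measuring it between two independently noisy,
independently self-normalized campaigns would instead measure mostly
the noise itself: the maximum over ~20 points of a 0.2–0.3% per-point
difference essentially always exceeds 0.5%.

## Numerical choices and edge cases

* Domain: $\beta \in [0°, 90°)$ — the formalism is derived for the
  upper-half scan; out-of-range angles are errors, as are negative $x$,
  non-monotone scan coordinates, and non-positive readings.
* The closed-form geometry is validated against an independent 2-D
  coordinate oracle (explicit source/detector positions, vector angles
  via `atan2`) to $10^{-10}$ relative over 1000 random geometries.
* `beta_from_x` tolerance: $10^{-10}$° (Brent); the $\beta \to x \to
  \beta$ round trip is tested to $10^{-6}$°.
* With the reference geometry, $x(\beta{=}20°) = 71.70$ cm from the
  closed form; the commonly quoted figure for this setup is 71.9 cm, a
  few-per-mille difference consistent with rounded geometry constants.
  Similarly the Markus factor at the scan edge evaluates to 1.00252
  against the usually quoted 1.0026 — a last-digit difference explained
  by the rounding of $\phi$ to 6.6°.
* Problem sizes used throughout tests: 21-point scans (the reference
  design), 1000-draw oracle sweeps, 10-seed noise batteries — all run
  in seconds on one CPU.

## Command line

The `exec/gantryscan` script exposes the pipeline as subcommands
(`simulate`, `transform`, `fit-response`, `compare`, `report`) over the
CSV dialects documented in `read_profile_csv()`; raw machine gantry
angles (base 270° for the horizontal beam) are reduced to $\beta$ at
the I/O boundary via `gantry_to_beta()`, so the math core never sees
machine coordinates. All subcommands are deterministic functions of
their inputs, flags and seed.

## Known limitations

Declined (non-horizontal) beams, couch or collimator rotations and 3-D
ray tracing are out of scope; the formalism covers the horizontal
upper-half scan. Directional-response constants are empirical per
chamber, depth and SSD — they must be re-measured for other setups, and
the package deliberately refuses to extrapolate them quietly. The
synthetic beam is a plumbing oracle, not an electron-transport model.
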