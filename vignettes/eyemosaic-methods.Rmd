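---
title: "Methods: simulating the retinal sampling-station image"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating the retinal sampling-station image}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Animal vision starts at an array of *sampling stations* — ommatidia in
compound eyes, single photoreceptors (per spectral class) in camera eyes —
each estimating the photon flux arriving from one direction. No later neural
processing can recover scene information these stations missed, so the image
available at this stage bounds what the animal can see. `eyemosaic`
approximates that image for an eye watching a photograph.

Three angular parameters (all in degrees at the user interface; all
trigonometry is done in radians internally) describe one chromatic channel:

* the **vertical and horizontal interommatidial angles** φ_V, φ_H — the
  angular separation of neighbouring stations, which set sampling density;
* the **acceptance angle** ρ — the full width at half maximum of a station's
  Gaussian angular sensitivity, which sets optical blur.

The scene is reduced to its photograph: if the image (height *h* pixels)
subtends a vertical angle α at the eye, every calculation can pretend the
eye watches the photograph from the distance, in pixel units,

    d = h / (2 tan(α / 2)).

A station's color is the Gaussian-weighted average of pixel values

    C_n = Σ_i χ_i w_i / Σ_i w_i,   w_i = exp(−2.77 (α_i / ρ)²),

where χ_i is the value of pixel *i* and α_i its off-axis angle for station
*n*. The constant is kept as the conventional printed value 2.77 (≈ 4 ln 2,
which makes ρ the FWHM: a pixel at α_i = ρ/2 carries weight 0.5003). R, G
and B planes are averaged independently; the output mosaic fills each
station's cell with its averaged color, rounded half away from zero to
8 bits exactly once, at render time.

## Scanning vs. fixed-viewpoint mode

**Scanning mode** assumes the viewer inspects the image with side-to-side
movements, always looking perpendicularly at the plane. Stations then form a
regular hexagonal lattice: rows spaced `2 d tan(φ_V / 2)` apart, in-row
spacing `2 d tan(φ_H / 2)`, alternate rows offset by half a column
(pointy-top hexagons — the orientation that realises the row/column spacing
statement directly). One station is anchored at the exact image centre. The
off-axis angle is `α_i = atan(r / d)` with `r` the in-plane distance from
pixel to station centre. (A different section of the source tradition quotes
the row spacing without the half-angle, `2 d tan(φ_V)`; we adopt the
half-angle form throughout, as it is the one derived from the viewing
geometry above and carries the original citation.)

**Fixed-viewpoint mode** keeps the eye stationary on the normal through the
image centre. Hexagonal facets tile a quasi-sphere, so their projected
centres are not equally spaced: the central station is surrounded by
concentric rings, ring *n* carrying 6·n stations on an axis-aligned ellipse
with radii `d tan(Σ φ_Hm)` and `d tan(Σ φ_Vm)` (sums over m = 0 … n−1).
Interommatidial angles may grow with eccentricity through the quadratic

    φ_Xm = φ_X0 + m φ_X1 + m² φ_X2,   X ∈ {H, V},

clipped into user clamps `[phi_min, phi_max]`; the clamp is applied
uniformly to every evaluated term, including ring 0 (the source text does
not single out the central value, and a uniform rule keeps the model
monotone in its coefficients). Acceptance angles follow the same quadratic,
unclamped — clamps are specified only for φ. Stations are placed at constant
increments of the ellipse *parameter*, 360/(6n) degrees, starting at
12 o'clock and moving clockwise; the literal reading of "a constant angle"
as a parameter increment is one of two defensible choices (the other being
constant arc length) and is the one adopted, with phase 0 for every ring
since no starting phase is specified. Rings are added until the ellipse
encloses the image, or the cumulative angle reaches 90° — the planar
projection diverges there, so the grid truncates with a warning.

Cell boundaries in fixed mode are the perpendicular bisectors of segments
joining neighbouring centres, i.e. the cells are Voronoi regions. We use the
same rule in both modes (for the scanning lattice the Voronoi regions *are*
the hexagons), implemented as an exact nearest-centre assignment of every
pixel centre, with ties broken deterministically toward the lower station
id. Pixel centres sit at integer + 0.5 with the origin top-left and y
pointing down. The off-axis angle in fixed mode is the angle between the
eye→station and eye→pixel vectors.

In scanning mode a station is kept when its cell contains at least one pixel
centre (a cell overlapping the image only by a sliver thinner than a pixel
is dropped with it). In fixed mode all constructed ring stations are
retained — the ring structure is meaningful in itself — and peripheral
stations may simply own no pixels.

## Chromatic treatment

A single color photograph is processed channel by channel. For species whose
spectral sensitivities do not match a camera's RGB (most of them), up to
nine gray-scale photographs taken through different filters can be combined
through a weighting matrix **W**: output channel c of station n is
`Σ_f w_fc C_nf`. Entries of **W** are unrestricted finite reals — no sign or
normalisation convention is imposed, since the appropriate weights depend on
the filters and species — so recombined values may leave [0, 255] and are
clipped only at render time. With the identity weights on an image's own
R/G/B planes, the recombination reproduces direct processing exactly, which
the test-suite asserts bit-for-bit.

Each output channel may also carry its own spatial parameters (e.g. a finer
mosaic for the channel whose receptor type is most abundant). Channels are
then sampled on their own grids and the rendered planes merged per pixel —
the only merge rule consistent with each channel owning a distinct
tessellation. A nominally gray RGB input is accepted if its channels agree
within one 8-bit level (they are then averaged); otherwise it is rejected.

## Numerical choices

* **Truncation.** The station average formally runs over every pixel. For
  performance the implementation truncates at α_i > 2ρ, where the relative
  weight is exp(−11.08) ≈ 1.5 × 10⁻⁵; a unit test bounds the induced error
  at < 255 · 5 × 10⁻⁵ on random images, and an oracle test checks exact
  (10⁻⁹) agreement with an untruncated double-loop evaluation on a geometry
  where truncation drops no term. A station whose truncated support contains
  no pixel centre is evaluated untruncated, so truncation never changes
  which stations are computable; `trunc = Inf` disables it.
* **Rounding.** Station values stay in double precision through combination;
  rounding (half away from zero) and clipping to [0, 255] happen once, in
  the renderer.
* **Ties.** Pixels equidistant from two station centres go to the lower
  station id, making every grid, and therefore every rendered mosaic,
  bit-reproducible.
* **Pixel values.** χ_i is the stored 8-bit value; no gamma linearisation is
  applied (the procedure operates on image values as stored).
* **Degenerate inputs.** A one-pixel-high image yields a single grid row; an
  image smaller than one cell yields a one-station grid whose output is the
  global weighted mean; sub-pixel station spacing is allowed with a warning
  (the output is then just a slightly blurred input).

## The MTF validation harness

The pipeline's spatial fidelity is checked against the eye's modulation
transfer function. A square-wave grating of spatial frequency ν
cycles/degree (horizontal stripes of equal *angular* width, 0/255) is
rendered into an image subtending `n_periods/ν` degrees, processed in
scanning mode, and the modulation

    M = (I_max − I_min) / (I_max + I_min)

is measured over the horizontal band two periods tall centred on the image —
two stripes above and two below the central line, which is what fixes the
stripes horizontal. Stripe generation enforces at least 4 pixels per central
period and at least 6 periods per image. Because nothing in the procedure
ties the grating phase to the grid, the measurement averages 8 evenly spaced
phases plus one seed-controlled common offset and reports the per-phase
spread; the pipeline contains no other randomness.

For a *sinusoidal* grating the Gaussian acceptance profile gives the closed
form `M(ν) = exp(−3.56 (νρ)²)`. A *square-wave* grating, however, carries
4/π times the sine amplitude in its fundamental, so the band max/min
measurement tracks the square-wave response

    M_sq(ν) = min(1, (4/π) Σ_{k odd} (−1)^((k−1)/2) M(kν) / k),

which exceeds the sine MTF by up to ≈ 0.17 around νρ ≈ 0.3 and converges to
it at high frequency, where only the fundamental survives. Our measured
curves match this closed form to within ~0.03; with honeybee parameters
(φ_V = 0.9°, φ_H = 1.6°, ρ = 2.6°) the measured modulation at 0.25
cycles/degree is ≈ 0.28, in agreement with the behavioural discrimination
performance reported for honeybees at that frequency (proportion correct
0.65, i.e. 0.3 after rescaling to [0, 1]). The distinction matters when
comparing against the sine-wave Gaussian curve: at ν = 0.10–0.20 c/deg the
square-wave measurement sits 0.10–0.17 above it, a property of the
procedure, not an implementation artefact.

```{r}
library(eyemosaic)
bee <- eye_params(phi_h = 1.6, phi_v = 0.9, rho = 2.6)
tc <- mtf_curve(bee, nu = seq(0.05, 0.3, by = 0.05), seed = 1)
plot(tc)
```

## What the synthetic scenes do and do not show

All tests run on generated scenes: uniform fields, step edges,
checkerboards, square-wave gratings and a deterministic RGB test card. These
exercise the geometry, the averaging, the recombination algebra and the
frequency response exhaustively, but they are piecewise-constant,
noise-free, perfectly registered images: passing tests demonstrates the
*transformation* is correct, not that any particular parameter set describes
a real eye, and says nothing about camera calibration, filter choice or the
weighting matrix appropriate to a study species — all of which remain the
user's responsibility.

Problem sizes used by the validation harness: the MTF criterion runs
1000-pixel-high gratings at six frequencies and eight phases (a few minutes
on one CPU); all other checks use images between 32 and 128 pixels and run
in seconds.

## Known limitations

* The quadratic eccentricity model with elliptical rings is the only eye
  heterogeneity supported: no acute zones, regionally varying curvature, or
  non-frontal gaze.
* Each sampling station is assumed to report every color channel; for eyes
  whose ommatidia carry receptor subsets this overestimates chromatic
  spatial resolution.
* The mosaic is an information-content visualisation, not a percept: animals
  do not see hexagons.
* Deriving **W** from spectral sensitivities, receptor-noise color
  discrimination, diffraction or photon noise are out of scope.
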