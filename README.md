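# eyemosaic

Simulate the image available at the *sampling-station* stage of a nonhuman
eye — the ommatidial mosaic of a bee, the photoreceptor array of a lizard —
when it views a photograph from a given distance.

Visual ecologists asking whether a crab spider is visible to an approaching
honeybee, whether a mimic's pattern survives a predator's acuity, or at what
distance a display becomes resolvable, need the image *after* the eye's
optics and receptor spacing have discarded detail, not the raw photograph.
`eyemosaic` computes that image from three angular parameters of the study
species plus the viewing geometry.

## The model

An image of height *h* pixels subtending a vertical angle α is watched from
the effective distance (pixel units)

```
d = h / (2 tan(α/2))
```

Sampling stations are laid on the photograph either as a regular hexagonal
lattice with row spacing `2 d tan(φ_V/2)` and column spacing `2 d tan(φ_H/2)`
(**scanning mode**: the eye inspects the image with side-to-side movements),
or as concentric elliptical rings of 6·n stations projected from a
stationary eye, with optional quadratic growth of the interommatidial angle
with eccentricity (**fixed-viewpoint mode**). Station *n*'s color is the
Gaussian acceptance-angle weighted average over pixels

```
C_n = Σ χ_i exp[−2.77 (α_i/ρ)²] / Σ exp[−2.77 (α_i/ρ)²]
```

where ρ (degrees, FWHM) is the acceptance angle and α_i the off-axis angle
of pixel *i*. Each station's cell — its Voronoi region, bounded by
perpendicular bisectors between neighbouring centres — is filled with that
color. Up to nine gray-scale filter photographs can be recombined through a
weighting matrix (`R_n = Σ_f w_fR C_nf`), and each output channel may carry
its own spatial parameters. A validation harness measures the modulation
transfer function on square-wave gratings,
`M = (I_max − I_min)/(I_max + I_min)`, for comparison with the analytic
Gaussian MTF `exp(−3.56 (νρ)²)`.

## Worked example

A honeybee (interommatidial angles φ_H = 1.6°, φ_V = 0.9°, acceptance angle
ρ = 2.6°) viewing a 96×128 test card that subtends 60° vertically — roughly
a flower-sized scene at a few centimetres:

```r
library(eyemosaic)
img <- test_card(96, 128)
bee <- eye_model(eye_params(phi_h = 1.6, phi_v = 0.9, rho = 2.6))
m <- eye_view(img, bee, alpha_v = 60)
m
#> eye mosaic: 96 x 128 px, 3 channel(s), scanning mode
#>   stations per channel grid: 2363
m$grids[[1]]
#> sampling grid (scanning mode): 2363 stations, 96 x 128 px
#>   spacing: 1.741 px vertical, 3.096 px horizontal
write_image(m, "bee_view.png")
```

The 12,288-pixel scene collapses onto 2,363 stations: the viewing distance
is `d = 128/(2 tan 30°) = 110.85` px, so the 0.9° vertical interommatidial
angle spaces station rows 1.74 px apart. The mosaic image has the input's
pixel dimensions, with each cell flat-filled by its station's color.

The same run from the shell, with a config file that is also written next to
the output as provenance:

```sh
exec/eyemosaic render bee.txt        # bee.txt: documented key = value format
exec/eyemosaic mtf --phi-h 1.6 --phi-v 0.9 --rho 2.6 --nu 0.1,0.2,0.3
#> nu = 0.1 c/deg: modulation 0.9530 (sd 0.0070, 1707 stations)
#> nu = 0.2 c/deg: modulation 0.4794 (sd 0.0046, 380 stations)
#> nu = 0.3 c/deg: modulation 0.1412 (sd 0.0043, 170 stations)
```

The measured modulations are square-wave responses; see the methods
vignette (`vignettes/eyemosaic-methods.Rmd`) for how they relate to the
sine-wave Gaussian MTF and to honeybee behavioural data.

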