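---
title: "Measuring inner-retinal remodelling after optic neuritis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring inner-retinal remodelling after optic neuritis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(octinl)
```

## The scientific question

Optic neuritis (ON), the inflammatory demyelination of the optic nerve
common in multiple sclerosis, destroys retinal ganglion cell (RGC)
axons; retrograde degeneration then thins the retinal nerve fiber layer
(RNFL) and the combined ganglion cell + inner plexiform layer (GCL/IPL)
of the macula.  The deeper inner nuclear layer (INL) behaves
differently: after ON it tends to *thicken*, and a minority of eyes
develop microcystic spaces inside it.  The analysis this package
implements quantifies that relationship on radial macular OCT: it
segments the RNFL, GCL/IPL and INL on each B-scan, samples their
thickness at 36 paramacular points, detects INL microcysts, and then
asks — per eye, per subject-pair of eyes, and per grid point — whether
INL thickening is proportional to GCL/IPL loss.

Because clinical OCT datasets of this kind are not freely available,
the package pairs the measurement chain with a synthetic-data generator
that renders radial scan sets with known ground truth.  Every accuracy
claim made by the test suite is therefore a claim against a known
truth, not against another algorithm.

## The acquisition model and what the generator emulates

A scan set is six B-scans through the fovea at 30° steps, each 4.5 mm
long; the macular star protocol.  The generator reproduces, per slice:

* a layered retina with seven interfaces (ILM, RNFL/GCL-IPL,
  GCL-IPL/INL, INL/OPL, plus OPL/ONL, ONL/photoreceptor and RPE base so
  the outer retina looks right), each band filled with a realistic
  relative reflectivity (bright RNFL and photoreceptor/RPE complex,
  moderate plexiform bands, dark nuclear bands, near-black vitreous);
* a foveal pit: the three inner layers thin to zero following a
  Gaussian profile (`pit_radius_um = 350`, profile SD half of that),
  so the inner surface dips exactly as the layers collapse;
* partial-volume rasterisation, an axial Gaussian point-spread function
  (`psf_axial_sigma_um = 8`), multiplicative gamma speckle, and
  optional vertical vessel shadows (columns multiplied by an
  attenuation factor);
* elongated hyporeflective INL microcysts (below).

Defaults: axial calibration 3.9 µm/px; lateral calibration
`4500 / ascan_count`.  The clinical protocol averages ~100 frames per
line scan; the generator represents that only through the speckle shape
parameter (averaging N uncorrelated speckle fields multiplies the gamma
shape by ≈N), with `speckle_shape = 100`, i.e. ≈10 % multiplicative
noise.  The generator does **not** model OCT physics (no interferometry
or depth-dependent roll-off), motion artifacts, curved A-scan geometry,
real vascular trees, or pathology other than the INL microcysts, so
passing tests demonstrate correctness of the measurement chain under a
clean but realistically noisy geometry — not robustness to every
clinical artifact.

Layer thickness targets are exact by construction: the phantom scales
its base thicknesses so that the mean over the 36 grid points equals
the requested target, and its geometry is analytic, so ground truth is
available in fractional pixels at any sampling.

## Simulated cohorts

`cohort_spec()` holds the generative statistics: per-group
multivariate-normal layer thicknesses (defaults: control
32.2 ± 2 / 98.1 ± 5 / 39.6 ± 3 µm, ON 27.8 ± 4 / 69.3 ± 14 /
42.9 ± 6 µm for RNFL / GCL-IPL / INL) with the corresponding
inter-layer correlation matrices (control: GCL-IPL↔INL +0.65 and
near-zero RNFL couplings; ON: RNFL↔GCL-IPL +0.80, RNFL↔INL −0.61,
GCL-IPL↔INL −0.44; the ON matrix is positive definite, smallest
eigenvalue 0.17).  Draws are truncated at 1 µm — the simplest structure
matching reported means, SDs and correlations.

Fellow eyes are drawn jointly with the ON eye from a 6-variate normal
whose cross-eye block is `rho * Sigma`; `fellow_coupling = 0.8` is the
package's choice of a realistic within-subject anatomical correlation
(no published anchor exists for it; coupling 1 makes the eyes
identical, 0 independent).  Exactly `round(prevalence * n)` ON eyes are
flagged for microcysts (default prevalence 5/36), assigned at random
(or to the thickest-INL eyes with `cyst_assignment = "extreme"`).

## Microcyst injection

Cysts are ellipses with the major axis perpendicular to the layers
(axial 20–35 µm, lateral 12–25 µm), 3–10 per affected eye, placed
750–2000 µm from the fovea on the supero- and infero-nasal radial lines
(template lines 5, 6, 8, 9), and darkened to 30 % of the local
intensity.  Injection also thickens the INL locally — a smooth Gaussian
bump of the GCL-IPL/INL boundary sized so each cyst fits inside the
band with ≥6 µm clearance.  This mirrors the physical situation
(microcystic change expands the layer) and guarantees the measured-INL
coupling: an eye rendered with cysts measures strictly thicker than the
same eye rendered without.  A cyst that still cannot fit at render time
is skipped with a message, never silently displaced.

## Segmentation

The per-scan chain is: vessel-shadow detection and removal →
multi-scale median filtering → Canny edge detection → ordered boundary
tracing.  Where the published description stops at the component names,
the concrete choices below are this package's design.

**Vessel shadows.** A column is flagged when its retina-band mean drops
more than `k = 2.5` robust SDs below a 61-column rolling median *and*
at least 8 % below it; runs are dilated by 2 columns.  Columns within
400 µm of the detected fovea are never flagged: the fovea is avascular,
and the pit walls darken column means exactly the way a shadow does.
Flagged columns are replaced by per-row linear interpolation (runs at
the image edge by nearest-neighbour extension) and marked
`interpolated` in the output provenance.

**Median filtering.** Window sizes 3, 7, 15 are applied in sequence,
but only the 3×3 window runs as a full 2-D median; the larger windows
run laterally (a running median along each row).  A square window
taller than the thinnest band (the RNFL is often under 10 px) mixes
intensities across two interfaces and measurably biases edge positions
by ~0.5 px under multiplicative speckle; boundaries vary slowly
laterally, so wide lateral windows deliver the smoothing without the
bias.

**Canny.** Gaussian-smoothed (σ = 2 px) central-difference gradients,
non-maximum suppression over quantised directions (with axial maxima of
predominantly vertical gradients admitted as well, so the long
near-horizontal interfaces stay continuous), hysteresis with the high
threshold at 0.2 × the 99.9th-percentile gradient magnitude and the low
threshold at half of the high one.  Anchoring thresholds to the
strongest edge rather than to a bulk quantile keeps the map
gain-invariant while retaining the weaker interfaces, whose gradient is
only about a third of the vitreoretinal one.  The weaker interfaces
survive hysteresis because every boundary line converges onto the
strong merged edge at the foveal pit.

**Boundary tracing.** The four measured boundaries are extracted
top-down in anatomical order; each is the minimum-cost lateral path
through a cost field built from the polarity-signed axial gradient
(each interface has a known bright→dark or dark→bright direction), with:

* attraction concentrated on thinned axial ridge maxima above the Canny
  low threshold, so the blurred tail of an adjacent interface exerts
  almost no pull;
* a smoothness penalty `lambda` (default 1 Canny-high-threshold unit
  per pixel of vertical jump, jumps capped at 2 px/column);
* a band constraint below the previously traced boundary, capped at a
  per-layer maximum plausible thickness (RNFL 90, GCL/IPL 160, INL
  90 µm) so a boundary cannot lock onto the next interface of the same
  polarity;
* a weak "glue" attraction (1.2 units) at the previous boundary's row,
  with all other attraction suppressed within ±1 px of it.  Inside the
  pit a collapsed boundary's own edge vanishes; the glue lets it ride
  on the surface above it exactly there, while being too weak to
  compete with any true edge on the flanks.

Ordering (non-crossing) holds by construction; if no admissible path
exists, the boundary and all deeper ones are flagged `failed` and
returned as `NA`, never fabricated.  Integer paths are refined to
sub-pixel precision on the *unsmoothed* median-filtered gradient — the
smoothed gradient's neighbouring-interface tails would bias the vertex
— using a weighted 7-row least-squares parabola (end weights tapered),
clamped to ±1.5 px.

Measured accuracy on phantoms (outside the central 500 µm, where the
protocol samples): noise-free mean absolute error ≤ 0.2 px per
boundary; at default speckle ≤ 0.6 px, with per-layer thickness biases
below 0.7 µm.  Inside the pit the inner interfaces coincide and no
image evidence defines their individual positions — which is exactly
why the measurement protocol excludes the central points.

**Quality gate.** Signal strength is the retina-band power over the
vitreous power (rows above the band; rows below carry the blurred tail
of the bright outer retina), in dB, gated at 25 dB; centration is the
distance of the detected pit from the scan centre (≤ 500 µm);
brightness uniformity is the brighter/darker lateral half ratio
(≤ 1.3).  A scan with zero background variance reports +Inf SNR and
passes that criterion.

## Thickness sampling

Twelve half-lines × three eccentricities give the 36-point grid.  Line
`l` points along `(l − 1)·30°` counterclockwise from the temporal
horizontal of a right eye; left eyes are mirrored onto this template
(θ → 180° − θ), so lines 5–6/8–9 are always the supero-/infero-nasal
obliques and quadrant semantics are eye-independent.  Default
eccentricities are 750/1450/2150 µm: the inner limit enforces the
central exclusion (boundaries are unreliable in the pit), the outer
limit leaves room for the 5-column averaging window inside the scanned
half-line — a sample at exactly half the slice length would sit on the
outermost A-scan and could not be averaged.  Thickness is the boundary
row difference × axial calibration, averaged over 5 columns to
suppress single-column jitter; a point whose window crosses a failed
boundary or the scan edge is invalid, never extrapolated (at the scan
edge the window keeps its in-range columns if at least 3 remain).  An
eye with fewer than 30 of 36 valid points is flagged unanalyzable.

## Microcyst detection

Within the traced INL band, pixels below `(1 − 0.35)` × a local INL
median (per-column medians smoothed by a 201-column rolling median —
robust to lateral shading) are candidates after a 3×3 median prefilter
that suppresses isolated speckle minima.  Connected components are
kept if they have ≥ 6 px², lie fully inside the band with 1 px margin,
are at least 0.8× as tall as wide (admitting near-round cysts while
favouring the perpendicular elongation), and show a rim/interior mean
intensity ratio ≥ 1.3 — the quantitative reading of
"well-circumscribed".  Columns with failed INL boundaries are excluded
from the search.  Reported extents are of the thresholded region and
therefore slightly underestimate the generative ellipse axes (the
partial-volume shell of a cyst sits above the threshold).

Prevalence is `100 × affected eyes / analysed eyes`, rounded to the
nearest integer percent; quadrants follow the line template (lines 1–3
supero-temporal, 4–6 supero-nasal, 7–9 infero-nasal, 10–12
infero-temporal).

## Statistics

Group comparisons use the pooled-variance Student t-test (two-sided;
Welch via `var_equal = FALSE`), correlations the product-moment r with
p from the t transform on n − 2 df.  Degenerate inputs are explicit:
both groups constant and equal → t = 0, p = 1 with a message; zero
variance in a correlation input → an error, never NaN.  No
multiple-testing correction is applied by default, matching the
original analysis convention (p < 0.05).

The asymmetry analysis subtracts the fellow-eye from the ON-eye layer
mean per subject (thinner ON-eye GCL/IPL → negative value), excludes
subjects without an analyzable fellow eye (binocular ON among them),
and correlates ΔGCL/IPL with ΔINL.  The point-wise deviation analysis
differences group means at each grid point; the map reports thinning
as positive for RNFL/GCL-IPL and thickening as positive for INL (the
usual deviation-map framing, stated in the output), while the
cross-layer correlation uses the signed ON − control differences for
both layers, so co-localised loss and gain give a negative r.  The
cyst subgroup comparison and the cyst-excluded correlations are
computed from one immutable measurement table, so "with" and "without"
results are directly comparable and reproducible.

Controls contribute one eye chosen at random, mirroring the clinical
protocol.

## Problem sizes and determinism

Simulation studies in the test-suite and the acceptance script render
at 768 A-scans × 160 depth pixels (axial calibration unchanged at
3.9 µm/px, lateral ≈ 5.9 µm/px): at this sampling a microcyst spans
several pixels in both directions and segmentation accuracy is within
the stated budgets, while a full 36-eye cohort segments in a few
minutes.  All randomness flows through explicit seeds (cohort draws,
per-eye speckle and cyst placement are derived deterministically from
the master seed plus subject/eye labels), so every pipeline run is
bit-reproducible; rendering is pure given (phantom, acquisition,
seed).

## Known limitations

* The GCL and IPL are treated as one band throughout (their
  reflectivities are too similar to separate), so GCL/IPL changes
  cannot be attributed to somata versus dendrites.
* Boundary positions inside the foveal pit are reported but carry no
  independent image evidence once the layers collapse; they are
  excluded from measurement by design.
* The detector's reported cyst extents underestimate true (generative)
  extents by the partial-volume shell; counts and localisation are the
  reliable outputs.
* The generator's speckle is spatially white; real OCT speckle has a
  correlation length comparable to the PSF, which would make the
  effective noise after filtering somewhat larger than the default
  setting emulates.
* No raster/volume protocols: the analysis is specific to the 6-slice
  radial pattern, and regions between radial lines are unobserved (so
  cyst prevalence per eye is, as in the clinic, a lower bound).
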