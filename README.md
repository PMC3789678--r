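# octinl

Quantifying inner-retinal remodelling after optic neuritis on radial
macular OCT.

Optic neuritis (ON) destroys retinal ganglion cell axons; retrograde
degeneration thins the macular retinal nerve fiber layer (RNFL) and the
combined ganglion cell + inner plexiform layer (GCL/IPL), while the
inner nuclear layer (INL) tends to *thicken*, and a minority of eyes
develop microcystic spaces inside it. `octinl` implements, end to end,
the measurement and analysis chain needed to study that relationship:

* **Synthetic data with ground truth** — a layered retina phantom with
  a foveal pit, rendered into radial B-scan sets (partial-volume
  rasterisation, axial PSF, multiplicative gamma speckle, vessel
  shadows, elongated hyporeflective INL microcysts), plus paired-eye
  cohort simulation with configurable group means, SDs, inter-layer
  correlation matrices and fellow-eye coupling.
* **Automated layer segmentation** — vessel-shadow detection and
  removal, multi-scale median filtering, Canny edge detection, and
  ordered boundary extraction by polarity-aware minimum-cost
  (dynamic-programming) paths with non-crossing enforced by
  construction, plus a scan quality gate (signal strength, centration,
  brightness uniformity).
* **36-point thickness sampling** — 12 radial half-lines at 30° steps,
  3 eccentricities per half-line; per-eye layer means for RNFL,
  GCL/IPL and INL.
* **Microcyst detection** — well-circumscribed hyporeflective regions
  confined to the INL band, with per-eye counts, sizes, radial-line
  and quadrant topography, and cohort prevalence.
* **Cohort statistics** — Student t group comparisons, inter-layer
  Pearson correlations per group, the inter-eye *asymmetry analysis*
  (ON eye minus fellow eye, removing inter-subject variability),
  covariate correlations, cyst-subgroup comparisons with and without
  flagged eyes, and the 36-point topographic deviation map with its
  cross-layer correlation.

Everything is tibble-first and pipe-friendly; fitted results have
`tidy()`, `glance()` and `autoplot()` methods.

At its core the analysis treats, for each group, the per-eye layer
means (x̄_RNFL, x̄_GCL/IPL, x̄_INL) over the 36 paramacular points, and
asks whether r(GCL/IPL, INL) flips from positive (healthy coupling) to
negative after ON — per eye, per subject pair
(Δ = ON − fellow), and per grid point (deviation from the control
mean). Boundaries are extracted as minimum-cost lateral paths through
the signed axial intensity gradient, with smoothness penalty λ per
pixel of vertical jump and anatomical ordering constraints.

## Worked example

Simulate one ON eye, render its six radial slices, segment them and
measure the grid:

```r
library(octinl)
acq <- acquisition_model(ascan_count = 768L, depth_px = 160L)
tr  <- simulate_cohort(cohort_spec(n_per_group = 2), seed = 2)
row <- tr[tr$role == "on", ][1, ]
es  <- render_eye(row, acq, seed = 2)
bds <- lapply(es$scans, segment_bscan)
grid <- sample_grid(bds, radial_protocol(), eye = row$eye,
                    subject = row$subject)
eye_summary(grid)
#> # A tibble: 3 × 7
#>   layer  mean_um n_valid n_invalid analyzable subject eye
#>   <chr>    <dbl>   <int>     <int> <lgl>      <chr>   <chr>
#> 1 GCLIPL    69.4      36         0 TRUE       P001    OS
#> 2 INL       47.3      36         0 TRUE       P001    OS
#> 3 RNFL      28.5      36         0 TRUE       P001    OS
```

The generative truth for this eye was RNFL 26.8, GCL/IPL 71.0, INL
47.4 µm: the measured means land within ~1.7 µm of truth on all three
layers, from pixels alone.

Cohort-level analysis on simulated ground truth (36 subjects per
group, the default generative statistics):

```r
tr <- simulate_cohort(cohort_spec(n_per_group = 36), seed = 1)
res <- analyze_cohort(tr)
res
#> Group comparison (per-eye layer means):
#>      layer  group1 group2 n1 n2 mean1 sd1 mean2  sd2     t  df        p
#>    rnfl_um control     ON 36 36  32.4 2.0  28.2  4.3  5.37  70  9.6e-07
#>  gclipl_um control     ON 36 36  99.7 4.4  70.2 13.9 12.15  70  6.7e-19
#>     inl_um control     ON 36 36  40.3 2.9  41.3  5.5 -0.98  70  0.33
#>
#> Inter-layer correlations by group:
#>    group         x         y     r  n ...
#>  control gclipl_um    inl_um  0.46 36   (positive in controls)
#>       ON gclipl_um    inl_um -0.46 36   (negative after ON)
#>
#> <asymmetry_result> 36 subjects (0 excluded)
#>   corr(dGCL/IPL, dINL): r = -0.51, p = 0.00131
```

The control-group GCL/IPL–INL coupling is positive, flips negative in
the ON group, and strengthens when inter-subject variability is
removed by the paired-eye asymmetry analysis — the qualitative
signature the pipeline is built to measure. (At n = 36 per group a
single simulated draw may or may not reach significance on the small
INL group difference, as here with p = 0.33; the correlation structure
is the robust readout.)

The full pipeline — simulate, quality-gate, segment, measure, detect
cysts, analyse, write CSV/JSON artifacts — is one call:

```r
run_pipeline(pipeline_config(n_per_group = 8, seed = 1), out_dir = "run1")
```

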