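# lamellometer

Thickness and quality control for cryo-FIB lamella fabrication.

Cryo-electron tomography resolves molecular structure inside cells only
when the imaged section — a lamella milled out of a frozen-hydrated
cell with a focused ion beam — is 100-200 nm thick. Milling thin enough,
uniformly enough, *and* through the right fluorescent target is the
yield-limiting step of the whole workflow, and it is usually flown
blind. `lamellometer` is an R toolkit for the people who run and build
that workflow: it provides calibration-free, quantitative thickness
feedback from three independent physical signals, a benchmark method,
and the optics correction needed to aim the mill at a fluorescent
structure buried in ice.

Four thickness methods share one `thickness_map` container:

* **Geometric (RLM)** — milling at angle θ leaves a tapered wedge whose
  bright footprint of width *w* in a reflected-light image gives
  *d = w·sin θ*. Robust from ~2 μm down to ~400 nm; per-frame
  thickness-vs-time monitoring during milling.
* **Thin-film interference (TFI)** — reflected intensity oscillates as
  *r(d) = r_mea + r_A·e(d/L)·cos(4π d n₂/λ + π)*; per-pixel
  least-squares inversion over one interference branch (period
  λ/2n₂ ≈ 181 nm in the blue), anchored on the geometric estimate,
  yields nm-scale thickness maps below ~500 nm.
* **q4STEM** — per-probe transmitted-electron scattering patterns are
  reduced to an integrated dark-field/bright-field ratio and inverted
  through a Monte-Carlo lookup table (screened-Rutherford elastic
  scattering + continuous slowing-down energy loss of 30 keV electrons
  in amorphous ice), with a cos(incidence) path-length correction.
  Works below ~1 μm with no instrument calibration.
* **EFTEM** (benchmark) — zero-loss log-ratio mapping,
  *t = λ_inel·ln(I₀/I)*, baseline-corrected on vacuum and tilt-corrected.

Around them: refractive-index-mismatch axial scaling for fluorescence
targeting (a dry NA 0.85 objective imaging into ice at n₂ = 1.28
compresses depth by S ≈ 1.39, i.e. ~280 nm of focal shift per μm),
asymmetric milling-pattern placement, quantitative map comparison, and
synthetic generators that emulate every modality from a known
ground-truth phantom.

## Worked example

```r
library(lamellometer)

# Targeting: how far does the axial coordinate shift in ice?
m <- axial_scaling_model(na = 0.85, n1 = 1.0, n2 = 1.28)
m
#> Axial scaling model: NA 0.85, n1 1.000 -> n2 1.280 (linear to 9.0 um)
#>   scaling factor S = 1.3881 (paraxial bound 1.2800)
place_asymmetric_pattern(m)
#> Milling pattern placement: bottom 0.30 um below, top 2.82 um above coincident point (S = 1.388)

# Geometric thickness from a measured wedge width
thickness_from_wedge(15.3, 10)   # 2657 nm  (~2.6 um lamella)
thickness_from_wedge(2.5, 10)    #  434 nm  (thin lamella)
milling_angle_from_defocus(4, 22.4)  # 10.3 deg: milling angle check

# Thickness-vs-time during milling, on a synthetic thinning series
p  <- tfi_params()                              # 463 nm, n2 from table
ph <- make_phantom(45, 8, 2600, theta_deg = 10) # ground-truth lamella
sim <- mill_simulation(ph, mill_rate_nm_s = 2.4, frame_interval_s = 120,
                       n_frames = 9, noise_sd = 0.02, seed = 3)
r  <- render_rlm_series(sim, p)
thickness_time_series(r$series, theta_deg = 10)
#>   t_s   w_um   d_nm           flag
#> 1   0 14.983 2601.7 above_validity
#> 2 120 13.283 2306.6 above_validity
#> 3 240 11.684 2028.8 above_validity
#> 4 360  9.983 1733.5             ok
#> 5 480  8.385 1456.0             ok
#> 6 600  6.695 1162.5             ok
#> 7 720  5.021  872.0             ok
#> 8 840  3.423  594.3             ok
#> 9 960  1.730  300.4 below_validity
```

The table tracks the simulation's ground truth (2600 nm thinning at
2.4 nm/s) to within a pixel-width of wedge, and the flags mark where
the geometric method leaves its reliable 400-2000 nm window.

```r
# q4STEM: Monte-Carlo lookup table and inversion
tab <- build_table(c(100, 200, 300, 400, 500), n_electrons = 8000, seed = 6)
tab
#> MC lookup table: 5 thicknesses 100-500 nm, 30 keV, amorphous H2O, 0.94 g/cm^3
#>   BF cutoff 60 mrad, acceptance 218 mrad, 8000 e-/point, seed 6
#>   thickness_nm df_bf_ratio          se
#> 1          100   0.3202737 0.008505511
#> 2          200   0.7274432 0.017160901
#> 3          300   1.1982434 0.028744268
#> 4          400   1.7541254 0.044643257
#> 5          500   2.4080742 0.066912648
```

The DF/BF ratio rises strictly with thickness — that monotone column is
what `thickness_from_pattern()` inverts (then multiplies by
cos 52° for the beam's angle of incidence). See the vignette
(`vignettes/thickness-control.Rmd`) for the models, parameter defaults
and the numerical conventions behind each step.

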