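---
title: "Thickness and quality control for cryo-FIB lamella fabrication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thickness and quality control for cryo-FIB lamella fabrication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Cryo-electron tomography needs lamellae 100-200 nm thick, milled out of
frozen-hydrated cells with a focused ion beam. `lamellometer` implements
the quantitative, calibration-free feedback loop around that process:
three complementary thickness measurements (geometric, interference,
transmission scattering), an energy-filtered TEM benchmark, and the
axial targeting correction needed to aim the mill at a fluorescent
structure buried in ice. A synthetic-data layer emulates every modality
from a known ground-truth thickness field, so each pipeline's recovery
error is measured, not assumed.

## Axial targeting under refractive index mismatch

A dry objective (`n1 = 1`) focusing into vitreous ice (`n2 = 1.28` at
109 K) compresses the microscope's axial coordinate: an emitter at
actual depth `z_A` appears at nominal depth `z_N = z_A / S`. Up to about
9 um the compression is depth-independent, so one scalar `S` suffices.

The high-NA value of `S` is computed by averaging the ray ratio
`tan(theta_1)/tan(theta_2)` uniformly over the aperture
(`sin(theta_1) <= NA/n1`, Snell refraction linking the two angles).
This average sits between the paraxial bound `n2/n1 = 1.28` and the
marginal-ray ratio (~1.82); for NA 0.85 it evaluates to `S = 1.388`,
i.e. a focal shift of ~280 nm per micrometer of actual emitter depth
and ~2.5 um at the 9 um linearity limit. The averaging scheme is
exposed (`scheme = "aperture_mean" | "paraxial" | "marginal"`) because
the exact weighting of aperture rays is a modelling choice; all three
stay within ~15% of each other's shift predictions at this NA. Shifts
can be quoted per actual or per nominal depth (`convention`); the two
are related by `S` and both are exactly linear in the linear regime.

Pattern placement follows directly: because compression always moves
the emitter *away* from the objective, the bottom milling pattern needs
only a small safety margin (default 0.3 um) below the coincident point,
while the top pattern must clear the worst-case shift
`max_nominal_depth * (S - 1)` (default anchored at the linearity
limit), landing ~2.8 um above it.

## Geometric thickness from reflected light

Milling at angle `theta` (default 10 deg) leaves a tapered wedge where
the lamella meets the foil. In a reflected-light image the wedge shows
as a bright band whose footprint width `w` along the lamella axis obeys

    d = w * sin(theta)

`extract_wedge_width()` averages the frame across the lamella width,
detects bands against a robust background (noise scale from first
differences of the profile, so the multi-level structure of a lamella
profile does not inflate it; detection threshold `k_sigma = 3`), picks
the band nearest the foil side, and reads the width at the
half-maximum-above-background crossings with sub-pixel linear
interpolation. The half-maximum criterion is a declared convention: the
worked examples constrain only the product `w sin(theta)`, and widths
are reproducible to ~1 px under affine intensity transforms. The
method is trusted between roughly 2000 and 400 nm; estimates outside
are flagged (`above_validity` / `below_validity`), never dropped.
`milling_angle_from_defocus()` verifies `theta` from the focus
difference across the lamella length.

## Thin-film interference

A uniform film of thickness `d` reflects

    r(d) = r_mea + r_A * e(d/L) * cos(4 pi d n2 / lambda + pi)

with a decaying envelope `e` accounting for scattering and coherence
loss (`L = 500 nm` by default). The printed form of the envelope is
typographically ambiguous between an exponential and a Gaussian decay;
both are implemented (`envelope = "exponential"` (default, following
the coherence-loss reading) or `"gaussian"`). All fitting happens on
min-max-normalised intensities, which removes `r_mea`, `r_A` and any
affine detector transform from the problem entirely — so the envelope
choice only matters well beyond one decay length. The refractive index
`n2(lambda, T)` comes from a packaged dispersion table; the shipped
table is a synthetic Cauchy-model stand-in anchored at the measured
mid-visible value 1.28 at 109 K and clearly labelled as such
(`asw_refractive_index_synthetic.csv`); substitute measured dispersion
data for quantitative multi-wavelength work.

Two fitting modes exist:

* `fit_trace()` — during constant-rate thinning, timestamps map to
  thickness decrements and only the global offset (the final thickness)
  is free. With the exponential envelope the normalised model is almost
  exactly self-similar under offset shifts of one period
  `P = lambda/(2 n2)` (~181 nm in the blue), so noisy global searches
  can alias by whole periods; the offset search should be confined to a
  window narrower than `P` around the geometric estimate, which is how
  the workflow uses it. Noiseless traces and Gaussian-envelope traces
  resolve the branch globally.
* `fit_thickness_map()` — per-pixel refinement of a thickness map over
  one interference branch `[init - P/2, init + P/2]`, anchored on the
  geometric estimate. Within a branch the cosine is two-to-one, so most
  intensities are matched on two flanks; among near-degenerate minima
  the fit takes the one closest to the initial estimate — branch *and*
  flank selection belong to the geometric anchor, the interference data
  supplies precision. The per-pixel objective is least squares on the
  normalised intensity, minimised by a 0.5 nm grid pre-scan plus
  parabolic refinement (deterministic, no random starts). Per-pixel
  normalisation bounds should come from the min/max over the observed
  milling series (`series_norm_range()`); the series must sample the
  oscillation finely (the real acquisition records a frame every
  ~10-15 nm of thinning) or the envelope estimate biases the fit.
  Fitting is only attempted below 1500 nm (`max_fit_nm`), where a
  constant-thickness region with clean interference exists; thicker
  pixels keep their geometric value and are flagged. An initial
  estimate one full period off lands exactly one period off — the
  documented failure mode of branch confinement.

`uniformity_sigma()` reports the population standard deviation over a
region of interest, the number quoted as lamella uniformity.

## q4STEM: thickness from transmitted scattering

With the lamella over a scintillator at camera length `D = 300 um`, a
scattering pattern is recorded per probe position; radius converts to
angle as `angle = arctan(r/D)` (33 um is ~110 mrad), and the detector
accepts up to 218 mrad. `radial_profile()` integrates equal-angle
annular bins (count-conserving by construction), and the thickness
observable is the integrated dark-field/bright-field ratio

    DF/BF = sum I(angle > cutoff) / sum I(angle <= cutoff)

The bright-field cutoff is a declared convention of the table, not a
physical constant. The package default is 60 mrad: the ratio-versus-
thickness curve saturates towards 1 um as multiple scattering pushes
intensity beyond both the BF disc and the 218 mrad acceptance, and a
larger disc keeps the curve strictly increasing up to 1 um at desk-
scale electron counts (2 x 10^4 per table node). On instruments the
cutoff can instead be measured from a vacuum-hole exposure
(`bf_cutoff_from_vacuum()`, 99% beam containment).

The lookup table is produced by `build_table()` from a Monte-Carlo
transport model authored in this package:

* screened-Rutherford elastic cross-sections per atom with the
  conventional screening parameter `3.4e-3 Z^0.67 / E` and the standard
  relativistic factor; free paths sampled exponentially from the total
  cross-section of H2O at 0.94 g/cm^3;
* continuous slowing-down energy loss between collisions (Joy-Luo
  modified Bethe stopping, valid at low keV), deposited at segment
  midpoints; no secondary-electron transport, no straggling;
* electrons tracked until they exit (transmitted/backscattered) or drop
  below 0.5 keV (absorbed); energy closes to bookkeeping precision by
  construction, and every stochastic operation takes an explicit seed.

At 30 keV in amorphous ice this gives an elastic mean free path of
~105 nm and stopping of ~0.85 eV/nm. Tables whose DF/BF column is not
strictly increasing are rejected with advice to raise the electron
count — statistical noise at that resolution would make the inversion
ill-defined. `thickness_from_pattern()` inverts the ratio by monotone
interpolation to a beam path length and multiplies by the cosine of the
beam's angle of incidence from the lamella normal (default 52 deg);
the most-common scattering angle (solid-angle-corrected histogram mode,
parabolic sub-bin refinement, ties broken toward the lower angle) is
reported as a consistency check. The method is useful below ~1 um;
near the top of that range the thickness standard error grows to
tens of nm because the ratio saturates.

The same transport run yields the radial distribution of deposited
energy around the incident axis, used to bound beam damage. For 30 keV
through 1000 nm of ice this model puts the radius enclosing 95% of the
deposited energy at ~0.3 um. That scale is corroborated by the
classical beam-broadening estimate
`b = 625 (rho/A)^(1/2) (Z/E0) t^(3/2)` (~0.4 um at these conditions):
lateral spread at 1 um depth is a few hundred nanometres in any
transport model with realistic elastic cross-sections. Figures of tens
of nanometres can only refer to much thinner sections or to a different
containment metric; the package reports the computed quantity as
defined. The containment radius grows monotonically with thickness, and
the one-collision angular distribution is chi-squared-tested against
the closed-form screened-Rutherford law.

## EFTEM benchmark

From an unfiltered/zero-loss image pair the thickness map is

    t = lambda_inel * ln(I0 / I)

with `lambda_inel = 320 nm` at 300 keV in vitreous ice, followed by a
baseline subtraction (mean over a vacuum region reads zero afterwards;
slightly negative noise pixels are kept to preserve that mean) and
division by `cos(pre_tilt)` (default 10 deg) to convert beam path to
lamella-normal thickness. Non-positive pixels are flagged and excluded
rather than propagated. The construction is exactly invariant to a
global exposure mismatch between the two images. `compare_maps()`
block-averages the finer of two registered maps onto the coarser grid
(thickness is a local mean, so block means are the faithful
down-sampling), then reports mean/SD of the difference and per-axis
mean profiles.

## Synthetic data, and what passing tests show

`make_phantom()` builds a 2.5D thickness field: linear wedges at both
ends with footprint `w = d / sin(theta)`, a flat plateau with optional
leading-to-trailing ramp, an optional platinum-rich band, and a vacuum
border. Renderers emulate each modality: reflected-light series
(interference reflectivity plus a bright foil-side band, additive
Gaussian noise at 2% of the rendered range), scattering patterns
(exit angles drawn from the transport model, azimuthally uniform,
projected as `r = D tan(angle)`; counting statistics arise from the
sampling itself), and EFTEM pairs (exponential attenuation, 1%
multiplicative noise). Noise defaults are plausible desk-scale regimes
and configurable; every generator returns its ground truth, and fixed
seeds give bit-identical output.

The phantoms are deliberately idealised: no ice-crystal contamination,
no curtaining, no spatially varying composition (a Pt-rich region in
real data reads thick, because the scattering table assumes pure
water — the known composition bias of the method, of order a few
percent for cellular material). Passing recovery tests therefore
demonstrate correctness of the *inference machinery* under the stated
noise models, not robustness to every artefact of real instruments.

Test problem sizes were chosen to make Monte-Carlo assertions sharp at
desk scale: 2-4 x 10^4 electrons per table node, 64 x 64 to
340 x 120 px phantom fields, 34-frame milling series. The full suite
runs in well under a minute.

## Numerical choices and degenerate inputs

* All optimisation is deterministic: grid pre-scans plus bounded local
  refinement (`optimize`, parabolic vertex); no random initialisation.
* Ties in the most-common-angle peak go to the lower angle, flagged
  `ambiguous`; flat profiles are `undefined` rather than a number.
* Flat intensity traces and traces covering less than one oscillation
  period raise `ambiguous-offset` errors instead of returning an
  arbitrary branch.
* Images are row-major with origin top-left and pixel centres at
  integer coordinates; pixel sizes are always explicit in sidecars.
* Wedge widths at frame edges are closed off half a pixel outside the
  frame; a band touching the edge is still measured.
* Stored maps and stacks are 32-bit float TIFFs with offset/scale
  recorded in a JSON sidecar; round trips are exact to float32
  precision. A corrupted sidecar degrades to a provenance warning, the
  values still load.

## Known limitations

* The transport model is single-scattering screened Rutherford with
  CSDA: adequate for DF/BF and containment observables, not for
  diffraction contrast, secondary-electron dose or crystalline
  material.
* The DF/BF inversion loses precision above ~800 nm as the ratio
  saturates; tables refuse to extrapolate outside their range.
* Interference fitting resolves thickness only within the branch and
  flank chosen by its geometric anchor; an anchor wrong by half a
  period gives a confidently wrong answer, which is why the geometric
  and interference pipelines are designed to run together.
* The dispersion table shipped for `n2(lambda, T)` is a labelled
  synthetic stand-in; only its 109 K mid-visible anchor is measured.
* Cross-method comparison assumes externally registered maps; no
  image registration is performed.
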