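---
title: "Dual-isotope SPECT: models, parameters and design choices"
author: "duospect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-isotope SPECT: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Holmium-166 radioembolization delivers radioactive microspheres to liver
tumours. Before treatment, a small "scout" activity of ¹⁶⁶Ho microspheres
(250 MBq) simulates the treatment distribution, and partition-model dosimetry
then needs the tumour and non-tumorous (healthy) liver delineated. A
dual-isotope protocol adds ⁹⁹ᵐTc stannous phytate, which accumulates in
healthy liver tissue, to the same SPECT acquisition: one scan yields a ¹⁶⁶Ho
image (the treatment surrogate) and a ⁹⁹ᵐTc image (the healthy-liver
delineation), and no CT-to-SPECT registration is needed.

The price is spectral crosstalk. ¹⁶⁶Ho's main photopeak sits at 81 keV and is
contaminated by downscatter from ⁹⁹ᵐTc's 140 keV photopeak; conversely the
140 keV window is contaminated by ¹⁶⁶Ho's high-energy gamma emissions and
bremsstrahlung continuum. `duospect` implements the whole evaluation loop for
this protocol on a digital phantom: simulation of the four-window
acquisition, OSEM reconstruction with window-based scatter compensation,
automatic healthy-liver segmentation, the image-quality metrics, and the
calibration of the downscatter scale factor *k*.

## Energy windows and scatter compensation

Four windows are acquired (centre, width as a fraction of the centre):
81 keV/15%, 118 keV/12%, 140 keV/15% and 170 keV/12%. Their absolute widths
are therefore $W_{81} = 12.15$, $W_L = 14.16$, $W_{PP} = 21$ and
$W_U = 20.4$ keV.

**Tc (140 keV) reconstruction — TEW.** Scatter in the photopeak window is
interpolated from the flanking windows:
$$S_E = \left(\frac{C_L}{W_L} + \frac{C_U}{W_U}\right)\frac{W_{PP}}{2},$$
with $C_L$, $C_U$ the counts recorded in the 118 and 170 keV windows. The
estimate is clipped at zero.

**Ho (81 keV) reconstruction — DEW.** The downscatter estimate is the 118 keV
window scaled by a single factor: $S_E = k\,C_{118}$. No window-width
rescaling is applied; by construction the optimal $k$ absorbs the width
ratio, which is why its numerical value is specific to this window scheme.
The toolkit treats $k$ as a free parameter swept over 0.65–1.30 in steps of
0.05 (built by integer stepping so the endpoints are exact).

## The simulator

The acquisition model is deliberately window-resolved rather than
keV-resolved. For each isotope, the *primary* term is the attenuated,
PSF-blurred parallel-beam forward projection of its activity map, scaled by a
photopeak sensitivity (counts·s⁻¹·MBq⁻¹) and the dwell time. *Downscatter*
terms are the primary-equivalent flux additionally blurred with a broad
Gaussian (σ = 30 mm) and scaled by window contamination coefficients:

* Tc contaminates the 118 keV window with a fraction `cTc118 = 0.10` of its
  primary flux, and the 81 keV window with `kTrue * cTc118`. The parameter
  `kTrue` (default 1.0) is the *generative* crosstalk ratio — the value that
  a perfect DEW correction should recover, which is what makes parameter
  recovery a meaningful test of the whole chain.
* Ho contaminates all four windows via `cHo` (81: 0.15, 118: 0.12,
  170: 0.08). The 140 keV coefficient defaults to the value a continuum
  reconstructed by the TEW interpolation would have,
  $c_{140} = (c_{118}/W_L + c_{170}/W_U)\,W_{PP}/2 \approx 0.130$. This is a
  deliberate design choice: the physical bremsstrahlung continuum is smooth
  enough for TEW to work well (the study's central observation about the Tc
  images), and a four-number window model can only encode "smooth enough" by
  making the interpolation exact. With an inconsistent choice (for instance
  $c_{140} = 0.10$), TEW would systematically over-subtract about 30% of the
  Ho contamination and the Tc images would *not* be independent of the Ho
  presence — the model, not the method, would be wrong.
* Nothing from Tc reaches the 170 keV window (140 keV photons cannot
  upscatter), so Tc-only acquisitions leave it empty.

Photopeak sensitivities default to 100 counts·s⁻¹·MBq⁻¹ for Tc — a typical
system sensitivity for a medium-energy collimator at 140 keV — and 7.5 for
Ho, about 13× lower, following the emission probabilities of the two gammas
(6.7% for the 81 keV Ho line against 89% for 140 keV Tc). This ratio is what
makes Tc downscatter a first-order contamination of the Ho window and
reproduces count-density swings of tens of percent across the k grid, the
effect size the calibration is designed to remove. The PSF is a
depth-independent in-plane Gaussian (σ = 5 mm). Attenuation maps mix
per-class coefficients (water from a standard table, e.g. 0.153 cm⁻¹ at
140 keV; lung 0.3 × water; air 0) weighted by fractional occupancy;
downscatter components are attenuated at the photopeak energy of the
originating isotope (a declared simplification). Decay and dead time are not
simulated: activities are "effective" — already compensated by dwell time,
as in the clinical protocol. The orbit is circular; Poisson noise is drawn
independently per bin from the expected counts under an explicit seed.

## The phantom

The default digital phantom mirrors an anthropomorphic thorax phantom: a
water-class torso, two lung-class lungs (zero activity), a liver ellipsoid
holding a 1205 mL healthy compartment, and two hot spheres S1 (24.2 mL) and
S2 (15.7 mL) carved out of the liver. Ho is distributed over healthy liver
and spheres at a 10:1 sphere-to-liver concentration ratio (so S1 carries
15.1% of the total activity); Tc goes only into the healthy liver. The
compartment list is ordered outermost first and later compartments carve
earlier ones, so occupancies sum to exactly 1 inside the body and sphere
voxels never count toward healthy liver. Shapes are voxelized by
supersampling (default 4³ sample points per voxel), which keeps compartment
volumes accurate to well under 1% on the 4.8 mm grid. The published phantom
gives no coordinates, so the liver sits in the upper-right body region with
both spheres ≥ 1 cm from the liver edge and > 2 cm apart — far enough to
preserve the spill-in/spill-over structure that the contrast and
segmentation metrics probe.

## Reconstruction

OSEM with the clinical settings: 10 iterations, 8 subsets, attenuation and
scatter correction, no post-filter. Design choices worth knowing:

* **Additive scatter.** The estimate enters the forward model
  ($x \gets x \cdot A^T\!\left[y/(Ax + s)\right] / A^T 1$) rather than being
  subtracted from the counts. This preserves Poisson statistics and
  nonnegativity. Whether the commercial implementation subtracts or models
  additively is not documented; additive is the numerically safer choice.
* **Projector.** A rotation-based attenuated parallel-beam operator with
  bilinear resampling; the back projector uses the transposed interpolation
  weights, so forward and back projection are exact adjoints and OSEM with
  one subset is plain MLEM for the matrix the operator defines (verified in
  the tests against an explicit dense-matrix MLEM). Attenuation uses the
  half-voxel self-attenuation convention. The same operator drives the
  simulator's primary term — an acknowledged inverse crime: reconstructions
  are more consistent with the data than any real system's would be. The
  phantom study conclusions this package reproduces are about *relative*
  behaviour (dependence on k, on Tc activity, on Ho presence), which
  survives the inverse crime; absolute contrast-recovery values do not.
* **Numerics.** Interleaved subsets (angle *i* → subset *i* mod 8), uniform
  initialisation on the body support (voxels with nonzero attenuation), a
  floor of 10⁻¹² added to forward projections before division, scatter
  estimates clipped at zero. Volumes are processed in a z-fastest memory
  layout, and the axial range is cropped to slices carrying attenuation or
  counts (padded by the PSF radius), which changes nothing outside slices
  that are identically zero.

## Segmentation

The healthy liver is segmented from the Tc image by thresholding at a
percentage α of the maximum of the Gaussian-smoothed image (σ in mm,
converted per axis to voxels; reflective boundaries so edge voxels are not
dimmed), with the threshold applied back to the *un-smoothed* image using an
inclusive (≥) comparison. Smoothing before taking the maximum removes the
dependence on a single noisy voxel. α is calibrated per scan so the
segmented volume matches the nominal 1205 mL: the segmented volume is a
non-increasing step function of α, constant between consecutive distinct
image values, so the calibration enumerates these plateaus, picks the one
whose volume error is minimal, and returns the plateau midpoint (a binary
image therefore calibrates to α = 0.5, the midpoint of the full range). A
series is segmented with the *average* of the per-scan optima; the smoothing
width is chosen by `selectSigma()` as the σ minimising the variance of the
segmented volumes, ties to the smaller σ. The shipped defaults (α = 0.40,
σ = 15 mm) are the published, scanner-specific values; the calibration
recomputes both for any synthetic series.

Cold spheres (tumours) are recovered from the mask as the holes of its
largest 26-connected component: morphological filling minus the component,
labelled and matched to nominal sphere centres by nearest centroid. A cavity
that touches the component boundary cannot be closed by filling; it is
reported as unrecovered rather than silently dropped. This hole-based
definition is this package's own; the published analysis used CT-registered
sphere VOIs.

## Metrics

* **COV**: 100 × population standard deviation / mean over voxels with VOI
  fraction ≥ 0.5, after a 1 cm ball erosion of the healthy-liver mask to
  avoid edge effects. (Whether the published COV used population or sample
  standard deviation is not stated; population is the image-uniformity
  convention and the difference is negligible at these voxel counts.)
* **Contrast recovery**: $Q = \frac{C_S/C_B - 1}{R - 1} \times 100\%$ with
  occupancy-weighted VOI means; R = 0 for cold spheres (Tc images), R = 10
  for the hot Ho spheres. Ground-truth phantom VOIs are used, mirroring the
  CT-defined VOIs of the published analysis; segmentation-derived VOIs are a
  separate path.
* **Volume recovery** (percent of nominal) and **Sørensen–Dice** on masks
  binarized at 0.5; two empty masks have Dice 1 by convention.
* **Count density**: occupancy-weighted mean voxel value per mL — fractional
  VOIs act as weights here (partial-volume aware) but are binarized for COV
  and erosion, which need a binary morphology.
* **COV–activity fit**: $COV(A) = \sqrt{a/A + b^2}$ by least squares (an
  L-BFGS-B fit with nonnegative parameters started from the linearised
  regression of $COV^2$ on $1/A$); b is the resolution-limited offset.
* **Welch t test** (two-sided, unequal variances) compares metric groups
  with and without Ho; identical constant groups return t = 0, p = 1.

## k-factor calibration

**Phantom mode** sweeps k over the grid, reconstructs every scan of a
fixed-Ho/varying-Tc series, measures the healthy-liver Ho count density and
expresses it as a percent change against the minimum-Tc reference scan. Two
summaries are reported side by side, because the published analysis uses
both framings: the least-squares slope of the change versus Tc activity, and
the percent error interpolated at a reference activity (default 50 MBq, the
clinical Tc amount; the default selection criterion). Under-correction
(k < kTrue) inflates the density, over-correction deflates it; the summary
is monotone in k and crosses zero near the generative ratio, so `selectK()`
(minimum absolute criterion, ties to the smaller k) recovers kTrue to within
a grid step. The zero crossing is not *exactly* at kTrue: at 10 iterations
OSEM has not fully converged, so a data shift common to y and s leaves a
small residual; the effect is a fraction of a grid step.

**Paired mode** mirrors the patient analysis: for each (dual, single) scan
pair the healthy-liver VOI is the thresholded Tc image of the dual scan, and
the per-pair percent difference in Ho count density (dual vs single, same k
for both) is summarised per k by median, IQR and median absolute value. A
pair whose Tc segmentation is empty is skipped with a warning. Dual and
single scans use independent noise seeds, as two separate acquisitions
would.

## The synthetic series and what passing tests mean

`generateFixtureSeries()` reproduces the study designs: the dual series
holds Ho at 250 MBq-equivalent with Tc log-spaced over 25–126 MBq (8 scans);
the Tc-only series spans 8–240 MBq; the paired series draws dual
(Ho 250 + Tc 50) and single (Ho-only) scans with independent derived seeds.
All randomness flows from one top-level seed expanded deterministically per
scan. The "small" scale runs a 64³ grid at 4.8 mm with 48 angles (the
clinical protocol uses a 128 × 128 matrix and 120 angles; 48 keeps the 8
interleaved subsets at 6 angles each), chosen so a full 14-point k sweep of
an 8-scan series is a desk-scale computation; count levels are kept at the
clinical sensitivities rather than scaled down, so Poisson jitter of the
density summaries matches the clinical scale. `scale = "paper"` switches to
the full matrix.

The generator emulates window crosstalk, attenuation, collimator blur and
counting noise. It does **not** emulate: keV-resolved spectra (so TEW's
adequacy is a modelling *assumption*, encoded in the TEW-consistent
`cHo["140"]` default, not a finding), non-circular orbits, depth-dependent
resolution, septal penetration, dead time, or mismatched
simulation/reconstruction projectors (a finer simulation grid is the
escape hatch if needed). Passing the parameter-recovery and independence
tests therefore shows the *analysis chain* is correct and self-consistent at
clinical count levels — it cannot certify the published absolute values
(contrast recovery 65.7%/57.8%, Dice 0.79/0.58/0.93, optimal k 0.95/1.05),
which depend on a real camera's spectra and resolution.

## Known limitations

* The window-resolved contamination model has no photopeak self-scatter for
  Ho (the published reconstruction ignores it too) and a single broad
  Gaussian as the spatial scatter model.
* The optimal k is meaningful only for this window scheme; different window
  settings require re-calibration (the sweep is the tool for that).
* Hole-based cold-sphere extraction under-segments spheres whose thresholded
  boundary merges with the liver edge.
* At 48 angles the reconstructions carry mild angular-undersampling texture;
  COV values are therefore not comparable in absolute terms with the
  published 128-matrix/120-angle numbers.
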