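---
title: "Simulating filter-based K-edge subtraction CT at a compact synchrotron source"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating filter-based K-edge subtraction CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kesct` is a self-contained simulation and analysis pipeline for
dual-energy K-edge subtraction (KES) CT performed with a
quasi-monochromatic inverse-Compton X-ray source and an iodine
transmission filter.  Its defaults encode the reference protocol the
package models: a source tuned to a 33.69 keV peak so the unfiltered
spectral mean (33.18 keV) sits just above the iodine K-edge at
33.169 keV, a ~290 µm effective solid-iodine filter that pulls the mean
below the edge for the second scan, 1000 projections over 360° at 44 ms
each, 70 µm effective pixels, and a porcine-kidney-like object with
iodinated vessels and a calcium-oxalate stone.  This vignette documents
the models, the calibrations, the numerical choices, and what the
simulation can and cannot say about real data.

## 1. The source spectrum

Inverse-Compton sources emit a quasi-monochromatic line: photon energy
is maximal for backscattering (`E_X ≈ 4 γ² E_L`, exposed as
`compton_peak_energy()`) and decreases off-axis, so a finite aperture
collects a sharply peaked spectrum with a low-energy flank and
essentially nothing above the peak.  The exact lineshape depends on
unpublished machine details (electron-beam emittance, laser bandwidth,
collimation), so the model has to be chosen; the constraints it must
satisfy are the published operating figures: mode at 33.69 keV,
bandwidth at most 4.5% FWHM, fluence-weighted mean 33.18 keV, and —
after the iodine filter — a mean of 32.59 keV.

`model_spectrum()` uses a **split-normal (two-piece Gaussian)** line:
a narrow Gaussian flank above the peak, a wider one below it.  The sum
of the two flank widths is fixed by the FWHM, so the profile keeps its
mode at the peak and its bandwidth at `fwhm_fraction * peak` by
construction, and a single asymmetry parameter (`tail_shape`) governs
how much weight sits in the low-energy flank.  That parameter is
calibrated once, by bisection, so the spectral mean equals 33.18 keV
(`calibrate_tail_shape()`); the filtered mean is then a *prediction* of
the model, and comes out at 32.61 keV — within the ±0.05 keV band that
is reasonable given the unpublished lineshape, and reproducing the
0.59 keV scan separation to better than 0.03 keV.

Two alternative families were evaluated and rejected during design:

* A Gaussian core with an *exponential* low-energy shoulder puts too
  much weight far below the edge: for any shoulder scale, by the time
  the unfiltered mean is pulled down to 33.18 keV the predicted
  filtered mean has saturated near 32.54 keV, and the amplitudes
  required destroy unimodality.  The measured filtered mean therefore
  rules this family out.
* A flat "aperture box" shoulder (the idealized angular-acceptance
  spectrum) can only reach the filtered mean with a shoulder taller
  than the Gaussian core, again losing the mode-at-peak property.

The energy grid is 15–60 keV in 0.025 keV bins: fine enough to resolve
the 0.57 keV mean shift with ~20 bins and to place the K-edge within
half a bin, wide enough to cover the entire emitted line.

### The above-edge remnant

Two distinct statistics describe what the filter does to the
high-energy part of the beam, and they differ by a factor of three:

* `above_edge_fraction(unfiltered, filtered)` — the **survival** of the
  above-edge intensity.  With 290 µm of solid iodine
  (µ/ρ ≈ 36 cm²/g just above the edge, areal density 0.143 g/cm²) this
  is `exp(-5.1) ≈ 0.6–0.7%`, and it is bounded below ~1.5% for any
  spectrum concentrated near the peak — a property of the published
  filter thickness and the attenuation data, not of the lineshape.
* `above_edge_share(filtered)` — the fraction of the *filtered* beam
  still above the edge, i.e. the visible above-edge remnant relative to
  the surviving spectrum.  The model gives 2.3%, the "few percent
  remnant" figure quoted for filtered spectra of this type.

The package computes both; the quoted ~3% can only refer to the second
statistic, since the first is physically pinned well below 1% by the
stated filter thickness.

## 2. Attenuation data

Packaged tables (`inst/extdata/attenuation/*.tsv`) cover the elements
and compounds of the experiment (iodine, calcium, gadolinium, water,
ICRU-44 soft tissue, whewellite, weddellite, PVP, air, plus H/C/O for
mixture cross-checks) on a 0.25 keV grid refined to 0.05 keV within
1.5 keV of an absorption edge.  Edge energies appear twice — the
below-edge then the above-edge value — and the interpolation rules are:
a query exactly at the edge returns the below-edge branch, any energy
strictly above uses the above-edge branch, and interpolation never
crosses the duplicated pair.  Between samples the interpolation is
linear in log(E)–log(µ/ρ), matching the power-law behaviour of
photoelectric cross-sections.

The tables are generated by `data-raw/make_attenuation_tables.py`:
photoelectric cross-sections from Cromer–Liberman f″ factors, coherent
scattering from IT92 atomic form factors (Thomson × F², integrated
numerically), and incoherent scattering from the Klein–Nishina cross
section weighted by the incoherent scattering function approximation
S(q) = Z − F²/Z.  Against standard reference tabulations the result
agrees to ~0.1–1.3% for iodine (the material that controls the filter
physics) and within ~2.5% for light elements, whose exact values the
pipeline's conclusions do not depend on: the phantom's two calibrated
materials are anchored to measured attenuation values, not to their
nominal compositions.

Mixtures follow the exact mass-fraction sum rule at evaluation time
(`make_mixture()`); note that the *packaged compound tables* satisfy
the sum rule exactly at their grid nodes but only to interpolation
accuracy (~1e-5) off-node, because log–log interpolation does not
commute with summation.

The air mass *energy-absorption* coefficients used for kerma are a
separate packaged table of standard reference values (10–100 keV,
log–log interpolated); µ_en/ρ is not derivable from the attenuation
tables without an energy-transfer model.

## 3. The phantom

`kidney_phantom()` generates the 2-D study object: a water bath inside
a 1 mm polymer beaker wall, an elliptical soft-tissue "kidney"
(ICRU-44), 3–10 circular vessel cross-sections inside it, and one
calcium-oxalate stone disc at the kidney surface.  The default grid is
512 × 512 at 70 µm voxels (matching the protocol's effective pixel
size); tests and the desk profile use 256 × 256 at 140 µm with the same
field of view.

Two properties are *calibrated*, because the physical quantities they
derive from are not published:

* the **vessel** material is iodine dissolved in water; its
  concentration is solved by bisection so that
  µ(33.18 keV) = 0.2184 1/mm — the measured vessel attenuation — giving
  ≈51.5 mg/ml, a plausible post-injection concentration;
* the **stone** is a 90/10 whewellite/weddellite mass mixture whose
  effective density is solved so that µ(33.18 keV) = 0.2105 1/mm,
  giving ≈2.0 g/cm³, close to the nominal mineral density — an
  independent consistency check of the attenuation tables.

Their contrast, 0.008 1/mm, is below the noise of a dose-matched scan:
the premise of the method (a single scan cannot separate them) holds in
the phantom by construction.

Vessel positions are the only random element (seeded rejection
sampling with a non-overlap constraint; a placement error is raised
after `max_tries` failures).  All physics is deterministic, and the
generator restores the caller's RNG state.

Primitives are hard-edged (no partial-volume blending), which keeps
region masks exact.  The one exception is the *analytic oracle*
`disc_phantom()`: its boundary voxels carry a one-voxel radial coverage
ramp, because a strictly binary disc quantizes chord lengths by about
one voxel (~2% error on interior rays) whereas the antialiased disc
tracks the closed-form line integral `2µ√(r² − s²)` to below 0.5%.

What the phantom does **not** emulate: anatomical kidney geometry,
contrast-agent diffusion into tissue, 3-D structure, and detector-level
effects (blur, scatter, rings).  Conclusions from passing tests are
therefore about the *method* — spectral shift, subtraction algebra,
reconstruction accuracy, noise propagation — not about anatomical image
quality.

## 4. Forward model

Projection is parallel-beam: at 15.3 m source–sample distance and a
~36 mm object, magnification varies by <0.2% across the object and the
cone angle is negligible.  The finite distances survive only in the
effective pixel size, `74.8 µm × 15.3/16.4 = 69.78 ≈ 70 µm`
(`effective_pixel_size()`).

`line_integrals()` implements the Radon transform by rotate-and-sum
with bilinear interpolation; its discretization error is bounded by the
disc oracle tests (<1% on interior rays).  `polychromatic_projection()`
computes per-region path-length sinograms once and reuses them across
energy bins:

    T = Σ_E w(E) Φ(E) exp(−Σ_m µ_m(E) L_m) / Σ_E w(E) Φ(E)

with `w(E) = E` for the energy-integrating scintillator detector
(`w = 1` available as a photon-counting option).  The energy sum runs
over quadrature bins of 0.1 keV (configurable) that never merge across
the K-edge; the spectrum itself stays on its fine grid for all spectral
statistics.  A single-bin spectrum reduces exactly to
`exp(−∫µ dl)`, which the tests assert at 1e-12.

The photon budget per detector pixel comes from the only published
normalization: total flux spread over the elliptic beam footprint
(62 × 74 mm² at the detector), giving ≈890 photons/pixel/projection for
the unfiltered scan at 74.8 µm pixels and 44 ms — low enough that shot
noise is a first-order feature of the protocol.  With `noise = TRUE`,
detected counts are Poisson draws with mean `N₀T`, flat-field
normalized by the expected incident counts (the flat itself is treated
as noiseless, i.e. acquired with long exposure).  Beam hardening is
real in this model: the edge-straddling unfiltered beam softens
(effective µ falls) with depth in iodinated water, and a monochromatic
beam shows none — asserted on slab sweeps.

## 5. Reconstruction

`fbp()` is standard parallel-beam filtered backprojection of
`−log(T)`.  Numerical choices:

* transmissions are floored at 1e-6 before the log (Poisson zeros at
  low dose); genuinely negative or non-finite rays are an error that
  names the offending rays;
* the ramp filter is applied in the Fourier domain using the DFT of
  the **band-limited spatial-domain kernel** rather than the ideal
  `|f|` response: with zero-padded projections the ideal ramp
  mis-handles the lowest frequencies and produced a uniform −3.2%
  attenuation bias; the band-limited kernel reconstructs a noiseless
  disc to 0.01%;
* a circular field-of-view mask zeroes voxels outside the inscribed
  circle, and ROI statistics use masks eroded by 2 voxels so
  edge-blurred voxels do not bias region means.

`sirt()` stands in for the statistical iterative method used on the
real scans.  It is a relaxed SIRT iteration
`x ← x + λ C A'(R (p − A x))` built on a **pixel-driven sparse system
matrix** whose exact transpose is the backprojector.  (An earlier
variant paired the rotate-and-sum forward operator with an
interpolating backprojector; the pair is not adjoint and the iteration
genuinely diverged after ~50 iterations.  With the matched pair the
residual decreases monotonically; residual growth in two consecutive
iterations is still treated as a convergence error.)  Early stopping
acts as regularization: at the default 50 iterations the noise in a
dose-matched reconstruction is several times lower than ramp FBP, at
the cost of a few percent quantitative bias — the classic trade-off of
iterative methods, and the reason the separation analysis below uses
SIRT while quantitative ROI recovery uses FBP on noiseless data.

## 6. KES analysis

`kes_subtract()` is the slicewise difference `unfiltered − filtered`
(signed, unclipped): the iodine image.  `inverse_kes()` multiplies the
filtered reconstruction by the energy-correction coefficient

    c = (Ē_unfiltered / Ē_filtered)³

and subtracts the unfiltered scan: `c·f − u`.  The cubic ratio
compensates the `1/E³` energy dependence of the photoelectric effect.
The published description of this coefficient does not fix which mean
energy is the numerator; the package uses the unfiltered-over-filtered
ratio (c ≈ 1.053 > 1) applied to the filtered volume, the direction
that produces the expected behaviour on the phantom — iodine strongly
inverted, stone brighter than the tissue background — and both the
coefficient and the direction can be overridden (`correction`
argument).  The mean energies are taken from the scans' spectral
metadata, never entered twice.

With the vessel calibrated at the above-edge energy, its monochromatic
attenuation drops from 0.2184 to 0.069 1/mm across the edge.  Under the
*polychromatic* unfiltered beam (45% of which lies below the edge) the
vessel's effective reconstructed attenuation is ≈0.138 1/mm — the
spectral average across the edge.  The monochromatic chain at the scan
mean energies is therefore the one that reproduces the measured ROI
values, and it is what the quantitative recovery test uses; the
polychromatic chain is used for everything where spectral realism
matters (noise, beam hardening, the KES contrast itself).

### Why the separation analysis runs at matched dose with SIRT

"The stone is eliminated from the iodine image" is a claim *relative
to the image noise*: across a 0.57 keV separation the stone's
attenuation genuinely changes by ≈0.009 1/mm (its photoelectric `1/E³`
slope), so its KES residual is not zero.  In a noiseless FBP
reconstruction the artifact floor is ≈0.002 1/mm and the stone residual
stands 3.9 standard deviations above it — visibly *not* eliminated.
At the protocol's actual photon budget the per-voxel noise is an order
of magnitude above the residual, and with a regularized (iterative)
reconstruction the vessels still stand >8σ above the background.  The
separation criterion is therefore evaluated on dose-matched noisy
scans reconstructed with `sirt()` (the reference experiment's method
class): stone |mean| < 3σ of the tissue background, vessel mean > 5σ,
iodine inverted and stone positive in the inverse-KES volume, and a
threshold segmentation of the KES volume that finds vessel components
and zero stone voxels.  These margins hold across SIRT stopping points
from 30 to 80 iterations; ramp FBP satisfies neither clause pair at
any noise level, which is itself an informative statement about
filter-based KES at this dose.

## 7. Dosimetry

`air_kerma_rate()` evaluates `K̇ = Σ_E (Φ(E)/A) E (µ_en/ρ)_air(E)` on
the spectrum grid, with the beam area scaled to the position of
interest (`beam_area_at()`).  At the sample position the model gives
0.255 mGy/s unfiltered and 0.045 mGy/s filtered — the same order as the
reference protocol's reported 0.16/0.07 mGy/s but not equal, because
the published rates depend on beam-path attenuation and area details
that are not stated; they are deliberately not calibration targets.
`total_dose()` is protocol arithmetic: kerma rate × 44 s per scan,
summed, times a kerma-to-effective-dose coefficient.  The default
coefficient 0.2587 Sv/Gy is back-solved from the published 10.32 mGy →
2.67 mSv pair (the coefficient itself is cited but not printed there);
note the published per-scan rates (0.16 + 0.07 mGy/s × 44 s = 10.12
mGy) are visibly rounded relative to the published 10.32 mGy total —
the package reports unrounded values and leaves the discrepancy as is.

## 8. Problem sizes and determinism

The default configuration is the full protocol (512², 1000 angles).
The test suite and the `"desk-test"` profile run at 256² with 180
angles (same field of view, 140 µm voxels) — sizes chosen so the whole
suite completes in a couple of minutes while every claim is still
exercised through the full pipeline; the analytic-oracle tests use
128² discs where the closed form makes errors directly measurable.
`run_experiment()` is a pure function of its configuration: fixed seed
⇒ bit-identical artifact checksums, with per-scan noise seeds derived
as seed+1/seed+2.

## 9. Known limitations

* The spectrum is a calibrated phenomenological lineshape, not a
  computed inverse-Compton spectrum; angular-spectral correlation
  across the beam is ignored.
* No scatter, detector blur, fluorescence escape, or ring artifacts;
  the detector energy weighting is the ideal `w(E) = E`.
* The filter is pure solid iodine of the stated effective thickness;
  its polymer matrix would add a smooth few-percent attenuation that
  the calibration absorbs.
* 2-D slices only; the 3-D protocol is a stack of independent slices.
* Light-element attenuation is accurate to ~2.5%, inherited by the
  water/tissue background (the calibrated vessel and stone values are
  exact by construction).
* FBP at the protocol dose does not reach the per-voxel SNR of the
  regularized reconstruction the reference experiment used; SIRT with
  early stopping approximates it but is not the same algorithm.
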