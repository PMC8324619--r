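---
title: "Quantitative Tc-99m SPECT simulation and reconstruction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative Tc-99m SPECT simulation and reconstruction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`qspect` studies how acquisition and reconstruction choices affect
quantitative Tc-99m SPECT of the NEMA IEC body phantom: the number of OSEM
updates, the dual-energy-window (DEW) scatter weighting, the angular
sampling of the orbit, and Butterworth postfiltering. The pipeline is fully
synthetic — a voxelized phantom, an attenuated parallel-beam projector with
distance-dependent resolution, Poisson counting noise, and the same
projector inside the reconstruction — so every claim the package makes can
be checked against a known ground truth.

# Phantom model

The IEC body phantom is generated parametrically (`phantom_spec()`,
`build_phantom()`): six fillable spheres (10–37 mm) on a 57.2 mm ring in
the central transverse plane, a cylindrical polystyrene lung insert on the
axis, and a rounded-rectangle torso outline (300 × 230 mm, corner radius
77 mm). Default fills are the measured concentrations of the study setup:
85.1 kBq/ml in the spheres and 10.6 kBq/ml in the background (≈ 8:1), with
no activity in the lung insert. Attenuation is water
(0.154 cm⁻¹ at 140.5 keV, narrow beam) inside the body and 0.30 × water in
the lung insert.

Voxelization uses the center-in-sphere criterion: a voxel belongs to a
sphere iff its center lies within the radius. On the 2.21 mm grid this
reproduces the voxel counts of the CT-based VOI analysis closely (48 vs 46
voxels for the 0.5 ml sphere, 2454 vs 2438 for the 26.5 ml sphere, 4606 vs
4612 for the 49.9 ml background VOI); the counts are not forced to match
exactly because the scanner-side segmentation/resampling chain is not
public.

**Background VOI placement.** The 49.9 ml spherical background VOI sits on
the central transverse plane at `c(0, 70, 0)` mm: radially midway between
the lung insert surface (25 mm) and the body wall (115 mm along +y),
azimuthally opposite the two largest spheres. This clears the nearest
small spheres by about 6 mm and the cold lung insert by 22 mm — the latter
matters, because with a ≈ 12.8 mm FWHM response a VOI close to the lung
picks up its smoothed cold spill-in at low iteration counts. The placement
is configurable and validated at build time: overlapping VOI labels are a
configuration error, never silently truncated.

# Acquisition model

Two protocols cover 360° with two heads in 1200 s: *clinical*
(60 projections × 20 s, 6° steps) and *NEMA* (120 × 10 s, 3° steps).
Expected photopeak counts per bin are attenuated parallel-beam line
integrals of the activity, scaled by dwell time, per-head planar
sensitivity (72.3 cps/MBq by default; the measured 71.7/72.8 split is
configurable) and voxel volume.

The collimator–detector response is a Gaussian whose FWHM grows linearly
with distance from the collimator face: 3.8 mm at contact and 7.4 mm at
100 mm (LEHR), hence ≈ 12.8 mm at the 250 mm radius of rotation where the
phantom center sits. Projection is slice-by-slice (2D): the axial direction
is neither blurred nor coupled, which matches a "2D OSEM" reconstruction
model and makes axial truncation of the grid exact for the retained slices.

Scatter is modeled as a convolution surrogate: the scatter contribution in
the photopeak window is the primary sinogram convolved with a broad
Gaussian (60 mm FWHM) scaled to a scatter fraction of 0.30 — a typical
value for Tc-99m in a body-sized water phantom. The scatter-window signal
is defined as that contribution divided by `k_true` (default 0.175), so
DEW correction with `k = k_true` recovers the simulated scatter exactly in
expectation. This makes the object-specific weighting factor SCF = 0.41
the simulator's ground truth, while the vendor default SCF = 1.10
(k = 0.470) over-subtracts by the same factor ≈ 2.7 reported for the
physical phantom. Both windows are sampled independently as Poisson counts
from one deterministic, seed-derived stream.

What the generator does *not* emulate: energy-resolved transport (the
scatter surrogate has no object-dependent spatial structure beyond the
blur), septal penetration, detector dead time, axial blur, center-of-
rotation errors, and decay during the scan. Consequences for
interpretation are discussed under *Limitations*.

# Reconstruction

`osem()` is ordered-subset expectation maximization with the same
projector used for simulation (attenuation from the phantom's μ map,
optional resolution modeling) and the DEW estimate `k · scatter window`
as an *additive term in the forward model*, never subtracted from the
measured data — this preserves Poisson statistics and non-negativity.
Subsets take every `s`-th angle (round-robin) so each subset spans the full
arc; the estimate starts uniform on the body support and stops strictly
after the configured number of iterations. The four study parametrizations
are 2i/10s, 4i/10s, 5i/15s and 24i/10s (20–240 total updates).

The projector rotates each slice so rays run along a grid axis. Activity
is rotated in scatter (splatting) form, which conserves total counts
exactly at every angle; the attenuation map is rotated in sampling form.
Depth-dependent blur uses incremental 3-tap Gaussian diffusion toward the
detector plus a residual kernel, all symmetric, and the backprojector is
the exact algebraic transpose of the forward operator. Exactness of the
adjoint is what lets the test suite compare OSEM with one subset against a
dense-matrix MLEM implementation at 10⁻¹⁰ relative tolerance.

Counts are converted to activity concentration by the quantitative factor
QF = 1/(S · T · V_voxel) (MBq/cnt/ml), with S the mean planar system
sensitivity, T = 1200 s the total scan time and V_voxel = 0.01079 ml. The
projector normalization is chosen so this chain is exactly invertible: a
matched, noise-free, resolution-model-free reconstruction returns the true
concentrations to numerical convergence.

**Butterworth convention.** The postfilter gain is
H(f) = 1/(1 + (f/f_c)^(2p)), applied radially in 3-D, so H(f_c) = 0.5 and
the vendor's "power = 10" corresponds to exponent 20. Conventions differ
between implementations; this one is stated prominently because cutoff
behavior (not the DC gain) is what changes under the alternative
`(f/f_c)^p` form. The cutoff is given in cycles/cm and mapped to digital
frequency through the voxel size. Postfiltering applies only to the
diagnostic 2i/10s reconstructions, as in the study grid.

# Calibration

Planar sensitivity follows the NEMA-style ratio counts/(duration ×
activity) from a simulated point-source acquisition. The object-specific
scatter weighting factor is determined on a dedicated hot-sphere-in-cold-
water phantom (`scf_calibration_phantom()`, `calibrate_scf()`): the
acquisition is reconstructed at each candidate SCF and the candidate whose
total reconstructed sphere activity is closest to the truth wins, ties
toward the smaller SCF. Total-activity matching was chosen as the
objective because it is insensitive to the partial-volume redistribution
at the sphere edge; the sweep objective is unimodal on noise-free data,
which the tests verify by exhaustive grid evaluation. Calibration
reconstructions run at a high update count (24i/10s by default in the
validation runs): the total-activity objective must be evaluated at
quantitative convergence, since at 20 updates the total still carries a
few tenths of a percent of convergence bias, enough to move the selected
SCF by several grid steps. The calibration tank is sized to stay inside
the grid's inscribed rotation circle so that no view clips the object.

# Metrics and statistics

Per VOI the package reports the mean and population SD (divisor *n*, since
a VOI is an exhaustively enumerated voxel set, not a sample), the hot-spot
recovery coefficient HSRC = AC_rec/AC_real, SNR = (AC_sphere −
AC_bg)/SD_bg, and background noise N = 100 · SD_bg/AC_bg.

The statistical layer mirrors the study's workflow: Shapiro–Wilk per
group and Levene (mean-centered) across groups; Friedman across three or
more dependent protocols or an exact Wilcoxon signed-rank test for two
(exact for ≤ 25 blocks without ties); and paired t contrasts against the
clinical reference protocol (clinical acquisition, 2i/10s, SCF 1.10,
postfiltered) with Bonferroni–Holm adjustment. "ANOVA post hoc" tables in
the source study are underspecified; paired contrasts within a
repeated-measures frame are this package's interpretation, applied
per sphere volume. `holm_adjust()` is written out so the step-down rule is
hand-checkable; the tests verify it against `p.adjust()`.

# Problem sizes and numerical choices

The default study grid is 144 × 144 × 32 voxels at 2.21 mm. In-plane this
covers the full torso outline at the scanner's reconstruction pixel size;
axially it is a 70.7 mm slab centered on the sphere plane, which contains
every VOI with margin. Because projection and reconstruction are 2D
slice-wise, the slab is *exactly* equivalent to the central slices of a
longer volume, so nothing is approximated by the truncation; it simply
keeps a 16-cell study run in the minutes range on one CPU. The phantom
module's default grid is 144 × 144 × 64 for users who want more axial
coverage, and both are configurable up to the scanner's 256².

Further numerical choices:

* zero-division guards in the OSEM ratio and sensitivity division (bins
  with zero forward value contribute nothing, voxels with zero
  sensitivity stay zero);
* all-zero projection data returns a zero volume with a warning rather
  than failing;
* incremental blur weights are clamped to [0, 0.49] so every 3-tap kernel
  remains a valid smoother;
* reporting helpers round half-away-from-zero (the clinical convention),
  while all internal arithmetic is unrounded;
* seeds: every stochastic step derives its stream from one integer seed
  (`derive_seed()`), so a grid run is reproducible byte-for-byte.

# Validation design

Two kinds of checks validate the reconstruction chain. *Parameter
recovery* uses a matched model without resolution modeling (in both the
simulator and the reconstructor): with attenuation, scatter + DEW at
`k_true`, and the full calibration chain, the largest-sphere mean must
return the known 85.1 kBq/ml within a few percent after 240 updates. The
resolution model is excluded from this check deliberately: with a
≈ 12.8 mm FWHM at the phantom center, the sphere-edge frequencies sit in
the numerical null space of the blurred system, so the sphere-mean
plateaus near 0.93 of truth regardless of iteration count — a property of
deconvolution, not an implementation defect. With the full model the
package reproduces the realistic recovery regime instead (HSRC ≈ 0.90 for
the 37 mm sphere at 24i/10s), which is where the *directional* checks
operate: recovery rises with updates and with the object-specific SCF,
SNR falls with updates, background noise rises with updates, and the
background mean is insensitive to the iteration count on noise-free data.
The background-stability check is made across the three quantitative
iteration sets (4i/10s, 5i/15s, 24i/10s), where the noise-free spread is
about 1 %; the 20-update diagnostic setting still carries a few percent of
residual convergence transient in the deep background (noise-free spread
3.5 % when it is included), which is expected OSEM behavior for interior
regions of a strongly attenuating object at low update counts.

# Limitations

* The scatter surrogate is spatially structureless (one global fraction
  and kernel); object-specific scatter gradients, e.g. near the lung
  insert, are not represented. DEW self-consistency at `k_true` is exact
  by construction, so SCF-related comparisons here probe the weighting
  arithmetic, not the physics of scatter estimation.
* With the default scatter fraction of 0.30, over-subtraction at
  SCF 1.10 depresses the reconstructed background strongly (to roughly
  40 % of truth), a larger effect than physical cameras show; the
  between-SCF *directions* match the physical study, absolute background
  values at SCF 1.10 do not.
* Resolution modeling is in-plane only; axial partial-volume effects are
  therefore absent and recovery coefficients are slightly optimistic for
  small spheres.
* One noise realization per acquisition protocol is shared across its
  reconstructions, as in the physical study (one scan, many
  reconstructions); between-protocol p-values therefore carry the same
  caveat as the original tables. A multi-seed replicate mode
  (`run_grid()` with different seeds) can add error bars the physical
  study lacks.

# A small worked run

```{r, eval = FALSE}
library(qspect)
cfg <- study_config()
res <- run_grid(cfg, seed = 1)
eff <- summarize_effects(res$metrics)
eff[, c("variation", "delta_ac", "delta_hsrc", "delta_snr", "delta_noise")]
panel <- panel_from_records(res$metrics, "hsrc")
compare_dependent(panel)      # Friedman across the 16 protocols
plot_recovery_curves(res$metrics,
                     protocol_ids = grep("clinical.*scf1.10",
                                         res$grid$protocol_id, value = TRUE))
```
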