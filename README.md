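# qspect

Simulation and optimization of quantitative Tc-99m SPECT reconstruction of
the NEMA IEC body phantom.

## The problem

Quantitative SPECT (qSPECT) promises absolute activity concentrations
(kBq/ml) from gamma-camera images, but the numbers depend strongly on how
the data are acquired and reconstructed: the number of OSEM updates, the
dual-energy-window (DEW) scatter weighting, the angular sampling, and any
postfilter. `qspect` rebuilds that optimization study as a self-contained
in-silico pipeline for physicists who want to study those trade-offs with a
known ground truth:

* a voxelized digital twin of the IEC body phantom — six hot spheres
  (10–37 mm, 85.1 kBq/ml) in a warm background (10.6 kBq/ml, ≈ 8:1), a cold
  lung insert, water attenuation at 140.5 keV;
* a dual-head parallel-beam acquisition simulator (photopeak 140.5 keV
  ± 10 %, scatter window 120 keV ± 5 %) with Poisson noise, distance-
  dependent LEHR resolution (7.4 mm FWHM at 100 mm) and a convolution
  scatter surrogate, under two protocols of identical 1200 s scan time:
  clinical (60 × 20 s) and NEMA-oriented (120 × 10 s);
* 2D OSEM reconstruction with attenuation correction, resolution modeling
  and additive DEW scatter correction parameterized by the vendor scatter
  weighting factor SCF (k = SCF · W_sc/W_pk; SCF 1.10 ↔ k = 0.470,
  SCF 0.41 ↔ k = 0.175), plus an optional Butterworth postfilter
  (0.5 cycles/cm, power 10);
* quantitation through QF = 1/(S · T · V_voxel) with the planar system
  sensitivity S (72.3 cps/MBq), and object-specific SCF calibration on a
  hot-sphere-in-cold-water phantom;
* the study metrics per VOI — hot-spot recovery coefficient
  HSRC = AC_rec/AC_real, SNR = (AC_sphere − AC_bg)/SD_bg, background noise
  N = 100 · SD_bg/AC_bg — and the statistical layer (Shapiro–Wilk, Levene,
  Friedman/Wilcoxon, paired contrasts with Bonferroni–Holm adjustment);
* an experiment driver that expands the 16-protocol grid (2 acquisitions ×
  4 iteration sets × 2 SCFs, postfilter on the 2i/10s diagnostic cells) and
  emits tidy metrics and effect tables against the clinical reference
  protocol.

See `vignettes/qspect-methods.Rmd` for the model, its assumptions, and all
numerical choices.

## A worked example

```r
library(qspect)

cfg  <- study_config()            # IEC phantom, 144 x 144 x 32 at 2.21 mm
res  <- run_grid(cfg, seed = 1)   # simulate + reconstruct all 16 protocols
eff  <- summarize_effects(res$metrics)
eff[, c("variation", "delta_ac", "delta_hsrc", "delta_snr", "delta_noise")]
```

```
               variation delta_ac delta_hsrc delta_snr delta_noise
1              SCF: 0.41   17.283     0.2031     -7.17       -4.62
2  Iteration set: 4i/10s    9.100     0.1069    -35.21       48.68
3  Iteration set: 5i/15s   11.766     0.1383    -40.35       86.01
4 Iteration set: 24i/10s   14.698     0.1727    -45.21      185.74
5      Acquisition: NEMA   -0.527    -0.0062    -10.55        4.88
```

(Output at `seed = 1`; other seeds move the numbers, not the signs.) Each
row changes one parameter against the clinical diagnostic reference
(clinical acquisition, 2i/10s, SCF 1.10, postfiltered), for the largest
(37 mm) sphere and the background VOI. The directions mirror the physical
study: more updates and the object-specific SCF 0.41 raise the recovered
concentration (higher HSRC), while more updates cost SNR and amplify
background noise. At 24i/10s with SCF 0.41 the largest sphere reaches
HSRC = 0.86 (cf. 0.88 reported for the physical phantom).

Single pieces are usable on their own:

```r
scf_to_k(1.10, report = TRUE)        # 0.470
scf_to_k(0.41, report = TRUE)        # 0.175
mean_sensitivity(71.7, 72.8)         # 72.3 cps/MBq
compute_qf(72.3, 1200, 0.01079)      # 1.068e-3 MBq/cnt/ml
sphere_volume(37, report = TRUE)     # 26.5 ml
hsrc(72.3, 85.1, report = TRUE)      # 0.85
```

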