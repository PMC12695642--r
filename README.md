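# pxctsim

Desk-scale simulation and analysis of **ptychographic X-ray computed
tomography (PXCT)** of heavy-metal-stained, resin-embedded neural tissue.

PXCT images millimetre-scale biology nondestructively at tens-of-nanometre
resolution, but the attainable resolution is limited by radiation dose and by
dose-induced sample deformation ("softening" of the embedding resin during
acquisition). This package reproduces the computational pipeline behind that
measurement chain entirely from synthetic data, for method developers and
reviewers who want to exercise the algorithms without a synchrotron:

* **Phantoms** — seeded voxel phantoms with neurite tubes, mitochondria,
  nuclei and synaptic puncta on a cylindrical pillar, plus smooth,
  dose-indexed deformation fields (`make_phantom`, `make_deformation`).
* **Forward model** — parallel-beam phase projections (phase proportional to
  projected electron density), Fermat-spiral ptychographic scans with Poisson
  photon noise, and absorbed dose in Gy from energy-over-mass with the
  molar-mass-per-electron convention (1.9 g/mol)
  (`project`, `acquire_series`, `simulate_ptycho_scan`, `absorbed_dose`).
* **Phase retrieval** — difference map followed by conjugate-gradient
  maximum-likelihood refinement with >= 1 probe modes; constant/linear phase
  ramp removal (`difference_map`, `ml_refine`, `remove_phase_ramp`).
* **Tomography** — projection alignment, Hann/Ram-Lak filtered back
  projection, interlaced subtomogram splitting, multiresolution 3D optical
  flow between subtomograms, temporal flow interpolation, and
  deformation-compensated (nonrigid) reconstruction by warp-accumulate
  (`fbp`, `split_subtomograms`, `estimate_flow`, `nonrigid_reconstruct`).
* **Resolution** — Fourier ring/shell correlation with the 1-bit and
  half-bit information thresholds

  `T = (SNR + 2 sqrt(SNR)/sqrt(n) + 1/sqrt(n)) / (SNR + 2 sqrt(SNR)/sqrt(n) + 1)`,
  `SNR_total = 2^bits - 1`

  split-half FSC resolution (half-pitch at the first crossing), and the
  dose-resolution power law `res = a / dose^(1/4)` with 95% nonsimultaneous
  observational prediction bounds
  (`frc`, `fsc`, `fsc_split_half`, `bit_threshold`, `fit_dose_resolution`).
* **Synapse detectability** — annotation-node census by 300 nm single-link
  merging, census/query matching, false-positive hotspots, annotator score
  QC, and confusion metrics `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1`,
  `F_beta` with `beta = 2`
  (`build_census`, `match_detections`, `find_hotspots`, `clean_scores`,
  `captcha_confusion`, `dendrite_report`).

## Worked example

Simulate a deforming pillar, reconstruct it rigidly and nonrigidly, and
compare split-half FSC resolutions:

```r
library(pxctsim)

ph   <- make_phantom(64, voxel_size_nm = 20,                 # 64^3 @ 20 nm
                     rng_seed = 11, texture_sd = 0.08)
def  <- make_deformation(dim(ph$density), amplitude = 4,     # 80 nm peak
                         smoothness = 16, mode = "drift", rng_seed = 12)
plan <- acquisition_plan(n_angles = 96, n_subtomos = 4)
ps   <- acquire_series(ph, def, plan, rng_seed = 13, noise_sd_rad = 0.08)

fsc_split_half(ps, mode = "rigid")$resolution_nm      # 62.5
fsc_split_half(ps, mode = "nonrigid")$resolution_nm   # 60.9
```

The rigid reconstruction of the deforming sample resolves 62.5 nm; the
nonrigid reconstruction — which estimates the deformation between the four
interlaced subtomograms by 3D optical flow and compensates it during back
projection — recovers 60.9 nm, the desk-scale analogue of the
deformation-correction gain reported for real tissue pillars (a static
control, `acquire_series(ph, NULL, ...)`, lands at 58.9 nm: deformation
costs the rigid reconstruction 3.6 nm, and the flow correction wins back
about half of it). Across the five seeds of the acceptance experiment the
nonrigid resolution is strictly better in 5/5 cases.

Dose arithmetic uses the beamline-scale constants:

```r
absorbed_dose(flux = 7e8, exposure_total = 100, fraction_absorbed = 0.1,
              photon_energy_keV = 6.2, electron_moles = 1e-9)
#> 3659709   # Gy
```

And the detection metrics reproduce the printed confusion arithmetic:

```r
confusion_summary(TP = 13, FP = 3, FN = 7)
#> P=0.8125 R=0.65 F1=0.7222 F2=0.6771
```

## Command line

```sh
Rscript inst/cli/pxct.R phantom --size 64 --seed 1 --out out/phantom
Rscript inst/cli/pxct.R acquire --size 64 --angles 96 --subtomos 4 --amplitude 2 --out out/projs
Rscript inst/cli/pxct.R tomo --in out/projs --mode nonrigid --filter hann --out out/vol
Rscript inst/cli/pxct.R fsc  --in out/projs --mode rigid --out out/fsc
Rscript inst/cli/pxct.R captcha-sim --seed 1 --out out/captcha
```

Volumes and projection stacks are stored as plain-text TSV stacks with JSON
sidecars; annotations and curves as CSV. See the methods vignette
(`vignettes/pxctsim-methods.Rmd`) for the model, parameter and design
discussion.
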