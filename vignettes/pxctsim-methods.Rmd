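---
title: "Methods: desk-scale ptychographic X-ray tomography simulation and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale ptychographic X-ray tomography simulation and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pxctsim` re-implements, at desk scale, the computational chain behind
nondestructive X-ray ptychographic tomography (PXCT) of heavy-metal-stained,
resin-embedded brain tissue: a synthetic tissue phantom is imaged through a
simulated ptychographic/tomographic acquisition under accumulating radiation
dose, reconstructed rigidly and nonrigidly, and scored for resolution and for
synapse detectability. Everything runs on a single CPU with volumes of
32--64 voxels per edge; nothing requires beamline data.

## The forward model and its assumptions

**Phantom.** `make_phantom()` voxelizes a cylindrical tissue pillar (the
simulated analogue of a FIB-milled sample) at an isotropic pitch of 40 nm by
default. Materials are painted as labels — neurite tubes from persistent
random walks, mitochondria and a nucleus as ellipsoids, synapses as
high-density puncta seeded on neurite surfaces — and mapped to piecewise
constant electron-density values, optionally overlaid with a smooth
intra-material texture (`texture_sd`, default 5% of the density step). The
texture matters: variational optical flow needs intensity gradients, and real
stained tissue is not piecewise constant. Limitations are deliberate: no
membrane-scale texture, no vesicles, no resin chemistry; a green test
therefore establishes the behaviour of the *algorithms*, not instrument
realism.

**Phase projection.** A projection at angle $\theta$ rotates the volume about
the vertical $z$ axis (bilinear resampling) and integrates along the beam;
the phase is proportional to the projected electron density via a single
configurable constant `k_phase` (rad per density-unit nm, default $10^{-3}$).
The paper-scale quantitative electron-density calibration is not reproduced.
Fresnel/multislice propagation and detector point-spread are out of scope.

**Dose.** Absorbed dose is total absorbed energy over total mass:
$D = \Phi\, t\, f_{\mathrm{abs}} E_\gamma / m$, with the mass derived from
the electron count through the mean molar mass per electron of the
resin/stain mixture, 1.9 g/mol. Default beam parameters follow the
instrument scale: $7\times10^8$ photons/s at 6.2 keV. The absorbed fraction
is an input (the instrument derives it from diffraction data we do not
model). Deformation is indexed by *dose fraction*, not wall time, because
radiation damage tracks dose; dose accrues linearly during a scan.

**Deformation.** `make_deformation()` builds smooth displacement fields
from Gaussian-filtered white vector noise ($\sigma = \text{smoothness}/2$,
so the field autocorrelation reaches $1/e$ at the stated correlation
length), zero at dose fraction 0 and rescaled so the maximum displacement
norm over all control fields equals `amplitude`. The default temporal
profile is `"drift"` — one field scaled linearly with dose, the coherent
creep of a softening resin; `"walk"` instead accumulates independent
increments per control interval, giving less coherent motion. The
acceptance fixture uses 20 nm voxels, amplitude 4 voxels (80 nm, i.e.
sub-100 nm) and smoothness 16 voxels; these are chosen to reproduce the
qualitative rigid-versus-nonrigid gap, since no quantitative deformation
spectrum is published for the real samples — a stated world, not measured
physics.

**Ptychography.** Scan positions follow a Fermat spiral (golden-angle
azimuth, $r \propto \sqrt{k}$), with the scaling constant calibrated
numerically to the requested mean nearest-neighbour step. Diffraction
patterns are $|\mathcal{F}(P \cdot O)|^2$ scaled to a photon budget and
Poisson-sampled. Retrieval runs the classic two-projection difference map
(relaxation 1, alternating least-squares object/probe factorization as the
overlap projection) followed by conjugate-gradient maximum-likelihood
refinement — Poisson NLL by default, Gaussian amplitude as an option — with
optional extra probe modes seeded at 1% power. The beamline's structured
zone-plate illumination is replaced by a soft-edged disk; DM relaxation and
ML parameterization are conventional choices, not replicas of beamline code.
Constant and linear phase components — gauge freedoms of ptychography — are
removed by a least-squares plane fit before tomography, and every recovery
metric in the tests is computed after ramp alignment.

An honest desk-scale finding: the ML stage descends the likelihood
monotonically (accepted steps only) and satisfies its contracts — final
likelihood at or below the warm start, a weak second probe mode on
single-mode data — but on these small noisy scans it does not measurably
improve phase RMS against ground truth over the converged difference map;
the per-iteration least-squares factorization inside our DM already sits at
the data's noise floor. The tests therefore assert "no worse than DM within
2%" rather than a strict improvement, which we could not realize without
the beamline regime (structured probes, hundreds of positions, regularized
ML).

## Tomography

Rigid reconstruction is windowed-ramp filtered back projection (Ram-Lak or
Hann; frequency-domain filtering with 2x zero padding; weight $\pi/N$).
Projection alignment uses the simplified consistency argument: the vertical
mass center is rotation-invariant and the horizontal sinogram mass center
follows a sinusoid in angle; residuals are removed by subpixel resampling.
The full tomographic-consistency alignment of the original pipeline is
declared out of scope.

**Subtomogram interlace.** "Equally spaced angular ranges" is ambiguous
between contiguous angular blocks and interlaced sparse subsets. We chose
interlaced subsets — subtomogram $j$ takes every $k$-th angle in sorted
order — because each subtomogram must independently reconstruct as a
low-resolution snapshot of the sample, which a contiguous 45° wedge cannot.
The acquisition visits subtomograms one after the other, so each subset also
occupies a contiguous dose window. This choice is configurable.

**Nonrigid reconstruction.** Each subtomogram is FBP-reconstructed; 3D
optical flow (multiresolution Horn--Schunck, 3 pyramid levels, smoothness
weight $\alpha = 1$ on intensity-normalized volumes — raised to 2, with the
data term masked to the reconstruction cylinder, when registering noisy
subtomogram FBPs — and flow zeroed on a 2-voxel boundary margin) is
estimated from the lowest-dose (reference) subtomogram to every other; flows are interpolated piecewise-linearly in
time to every projection and clamped outside the node range; reconstruction
is warp-accumulate: back-project each filtered projection alone, warp that
partial volume onto the reference state with its flow, accumulate. Full
deformed-ray integration is out of scope. The flow convention is
gather/pull-back — `warp_volume(b, estimate_flow(a, b))` approximates `a` —
so the estimated field is directly the one needed to map a later snapshot
back onto the reference; the fixed-point field inversion (5 iterations,
0.01 voxel tolerance) is available where a forward/scatter field must be
inverted (e.g. comparing against the simulator's true deformation).

Two numerical choices deserve emphasis:

* **Flow pre-smoothing.** Subtomogram FBPs from few angles are noisy and
  streaky. The physical deformation is smooth (correlation length tens of
  voxels), so flows are estimated on Gaussian-smoothed subtomograms
  ($\sigma = 2$ voxels by default). Without this, the flow estimator fits
  reconstruction noise, and — because the same fields warp both split
  halves in the FSC workflow — noise-fit fields inject spurious half-to-half
  correlation and inflate the apparent resolution. With pre-smoothing, a
  null experiment (no deformation, realistic noise) yields nonrigid
  resolution equal to rigid within tolerance, which is the honest behaviour.
* **Shared flows across FSC halves.** In split-half FSC of a nonrigid
  reconstruction, flows are estimated once from the full series and applied
  to both halves, registering both to the same reference state. Estimating
  flows per half would register the halves to *different* deformation
  states and bias the FSC down; sharing them mirrors the source pipeline but
  means the halves are not fully independent through the (strongly
  smoothed) deformation model. The null experiment above bounds this
  leakage.

## Resolution metrics

FRC/FSC uses 1-Fourier-voxel shells, a soft spherical mask (cosine edge, 5%
width — a knob documented as a deviation, since the original analysis does
not state its apodization), and the van Heel information-bit thresholds.
`bit_threshold()` implements
$T = (\mathrm{SNR} + 2\sqrt{\mathrm{SNR}}/\sqrt{n} + 1/\sqrt{n}) /
(\mathrm{SNR} + 2\sqrt{\mathrm{SNR}}/\sqrt{n} + 1)$ with
$\mathrm{SNR}_{\mathrm{total}} = 2^{\mathrm{bits}} - 1$; the normalization
flag selects whether the per-half-dataset SNR (the canonical curves: 0.5 for
1 bit per compared image, 0.207 for half a bit) or the full-dataset SNR
(0.414 $\approx$ 0.4 for half a bit) enters and is reported. The resolution
workflow always uses the per-half normalization, i.e. the canonical curves.
Resolution is reported as half-pitch, $\mathrm{voxel}/(2 f_{\times})$, at
the first downward crossing (linear interpolation in frequency, DC shell
excluded); a curve that never crosses reports the band-limit sentinel
$2\times$ voxel size with a flag — deliberately pessimistic, so an
uncrossed curve never outranks a crossed one.

Split-half FSC reconstructs odd/even angular halves independently (each with
double angular spacing) and applies the half-bit criterion. The dose ladder
simulates rungs at increasing photon budgets with Gaussian phase noise
$\propto 1/\sqrt{\text{photons}}$ — the Gaussian approximation of
photon-limited phase error — rather than running full ptychographic
retrieval per projection, which module tests cover separately. The
dose-resolution law $\mathrm{res} = a\,/\,\mathrm{dose}^{1/4}$ is fitted
with the exponent fixed, so $\log a$ is the mean of
$\log r + \tfrac14 \log D$; the 95% prediction band uses nonsimultaneous
observational bounds, $t_{0.975,\,n-1}\, s \sqrt{1 + 1/n}$ on the log scale.

**Why the acceptance fixture uses phase noise 0.2 rad.** With noiseless
projections the split halves agree to the band edge and every
reconstruction saturates at the sentinel; resolution only discriminates
when the FSC is noise-limited. At 0.2 rad the static-sample resolution sits
mid-band (about 3x the voxel pitch), comparable to the real datasets'
resolution-to-pixel ratios, and that value was fixed before the
rigid/nonrigid acceptance comparison was run.

## Synapse detectability

The census follows the dendrite-centric procedure: annotation nodes within
300 nm merge single-link (chains merge; `hclust` cut at the radius, with a
brute-force BFS oracle in the tests), centroids are member means, and each
entry keeps the earliest pass at which it was seeded. Matching marks a
census entry detected if any query node falls within 300 nm of its
centroid; unmatched query nodes cluster into "hotspots" when at least two
fall within 300 nm. The captcha task scores 250 regions x annotators x two
modalities with confidences 1--4 (0 = no response). Cleaning drops
annotators whose reference-modality score vector has Pearson correlation
(our reading of the stated "cross-correlation", applied as a strict
inequality) below the threshold with the mean of the others, then drops
regions with any missing response. Region means at or above 2.5 binarize to
"synapse" (a tie at exactly 2.5 counts as synapse, per the stated $\geq$);
EM is the reference and PXCT the prediction; the 4x4 table bins rounded EM
means (ties away from zero) against PXCT score distributions. Precision
with no positive predictions is reported as missing with a flag, never as
zero. $F_\beta$ uses $\beta = 2$ so recall outweighs precision. The
per-dendrite "70 +/- 6%" style statistic is emitted alongside pooled counts
without asserting their equality, since the printed pooled counts cannot
recover a per-dendrite mean.

## Open design points, resolved

* The number of outer flow-refinement iterations in the original nonrigid
  algorithm is unstated; `n_outer_iters` defaults to 0 (single pass) and is
  exposed without claiming fidelity.
* "Modified" filtered back projection is unspecified; we implement standard
  windowed FBP.
* The band-limit sentinel is stated as $2\times$ voxel size even though the
  half-pitch at Nyquist is $1\times$; the sentinel is a flag value chosen
  pessimistically, not a physical resolution claim.
* I/O uses plain-text stacks (TSV slices + JSON sidecar) and CSV because no
  TIFF/HDF5 R package is available in the target environment; readers for
  those containers are out of scope for this build.

## What a green suite establishes

Deterministic generators, correct geometry (projection/FBP adjoint pair,
delta recovery), honest phase retrieval on synthetic scans, flow recovery of
known smooth warps, canonical FSC thresholds and a calibrated prediction
band, the printed confusion arithmetic, and — at desk scale — the
qualitative headline: under dose-driven deformation, deformation-compensated
reconstruction recovers resolution that rigid reconstruction loses, and
resolution improves with photon budget. It does not establish instrument
realism, absolute resolutions in nm, or human-annotator behaviour.
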