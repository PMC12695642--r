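Package: pxctsim
Title: Desk-Scale Simulation and Analysis of Ptychographic X-Ray Tomography of Stained Tissue
Version: 0.1.0
Authors@R:
    person("PXCT", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Simulates ptychographic X-ray computed tomography (PXCT) of
    heavy-metal-stained neural tissue at desk scale and analyses the results.
    Provides seeded generators for voxelized tissue phantoms with neurites,
    mitochondria, nuclei and synaptic puncta; smooth dose-dependent sample
    deformation models; Fermat-spiral ptychographic scan simulation with
    Poisson photon noise; phase retrieval by the difference map followed by
    maximum-likelihood refinement with multiple probe modes; projection
    alignment and filtered back projection (Hann or Ram-Lak); nonrigid
    tomographic reconstruction that estimates inter-subtomogram deformations
    by multiresolution 3D optical flow and compensates them during back
    projection; Fourier ring/shell correlation with 1-bit and half-bit
    information thresholds and split-half resolution estimation; absorbed-dose
    bookkeeping in gray; a dose-resolution power-law fit with prediction
    bands; and synapse-detectability scoring via annotation-node censuses,
    distance matching, hotspot detection and confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
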