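Package: fatnav
Title: Fat-Navigator Motion Tracking and Retrospective k-Space Motion
    Correction for Ultra-High-Resolution MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and retrospective correction of rigid-body head
    motion in multi-shot 3D Cartesian MRI. Provides seeded digital brain
    phantoms with a scalp-fat shell and smooth coil sensitivities,
    acquisition plans for MP2RAGE, 3D-TSE and 3D-GRE protocols (partial
    Fourier, GRAPPA, shot ordering, scan-time accounting), a
    motion-corrupted multi-channel k-space forward model, low-resolution
    fat-excitation navigator simulation with GRAPPA reconstruction and
    rigid registration based motion estimation, per-channel k-space
    correction via a 3D non-uniform FFT over rotated coordinates, MP2RAGE
    signal modelling with lookup-table T1 quantification, and
    post-processing utilities (bias-field correction, co-register and
    average, Fourier downsampling, point-spread-function and scan-economics
    analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
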