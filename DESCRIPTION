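Package: fiberfbm
Title: Simulation of Serotonergic Fiber Densities by Reflected Fractional
    Brownian Motion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models brain-wide serotonergic axon density patterns as the
    steady state of fractional Brownian motion walkers reflected inside a
    three-dimensional brain geometry. The geometry is a stack of coronal
    sections, each described by contour rows with allowed and forbidden
    regions; fibers advance by discrete fractional Gaussian noise increments
    (Fourier-filtering and circulant-embedding generators), steps that would
    leave the allowed region are rejected, and visited positions are pooled
    into 2x2x2 voxel bins, sum-normalized, and transformed to
    immunohistochemistry-like optical densities. Includes synthetic phantom
    geometries (slab, sphere, brain-like with ventricles and a dorsomedial
    concavity), Hurst-index estimation from mean squared displacement,
    border-distance density profiles, and NIfTI volume export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
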