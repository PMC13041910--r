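Package: plectotrace
Title: Tracing and Topological Quantification of Supercoiled DNA Plasmids
    from Cryo-ET Density Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the three-dimensional topology of
    supercoiled circular DNA imaged by cryo-electron tomography. The
    package recovers a closed duplex centerline from a single-particle
    density volume (spine-line skeletonization, sampling-cylinder weight
    centers, linking, smoothing), and quantifies plasmid morphology:
    Gauss double-integral writhe, circumscribed-circle curvature and
    plectoneme apex detection, radius of gyration from the gyration
    tensor, superhelical-axis tracing with inter-strand spacing, branch
    decomposition with per-branch writhe densities, and linking-number
    bookkeeping (supercoiling density, twist-writhe partition). Bound
    protein particles (e.g. RNA polymerase, dCas9) are assigned to the
    traced curve, classified as apical or off-apex, and mapped to
    fiducial-anchored base-pair coordinates. A synthetic-data module
    generates ground-truth interwound plectonemes, rendered density
    volumes and planted particles so the full pipeline is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
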