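Package: kesct
Title: Filter-Based K-Edge Subtraction CT at a Compact Synchrotron Source
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for dual-energy K-edge
    subtraction (KES) computed tomography with a quasi-monochromatic
    inverse-Compton X-ray source and an iodine transmission filter.
    Models the source spectrum and its filter-induced mean-energy shift
    across the iodine K-edge, renders kidney-like voxel phantoms with
    iodinated vessels and a calcium-oxalate stone, simulates paired
    polychromatic CT acquisitions with Poisson noise, reconstructs them
    by filtered backprojection or SIRT, separates iodine from calcium by
    KES and inverse-KES subtraction with the cubic energy-correction
    coefficient, and accounts air kerma and effective dose for the
    acquisition protocol.  Ships Cromer-Liberman-derived X-ray
    mass-attenuation tables with absorption-edge handling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
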