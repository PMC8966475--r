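Package: synapseflow
Title: Quantitative Imaging of Cytoskeletal Dynamics, Granule Motility and
    Traction Forces at the T-Cell Immune Synapse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An image-analysis pipeline for time-lapse microscopy of
    cytotoxic T lymphocytes spreading on stimulatory surfaces. Implements
    cell-footprint segmentation with hyperbolic-tangent spreading kinetics,
    center/annulus fluorescence intensity ratios, spatio-temporal image
    correlation spectroscopy (STICS) flow mapping with directionality
    statistics, point-emitter detection and gap-closing particle tracking,
    mean-squared-displacement analysis with anomalous-exponent
    classification, lytic-granule segmentation with radial profiling,
    regularized Fourier-transform traction cytometry (FTTC), the comparison
    statistics used on the derived measurements, and a synthetic-scene
    generator with known ground truth for every input modality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
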