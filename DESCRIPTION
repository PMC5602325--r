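Package: slimcluster
Title: Single-Molecule Slimfield Analysis of Transcription-Factor Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying transcription-factor clusters from
    millisecond Slimfield single-molecule fluorescence microscopy of live
    yeast cells. Provides synthetic Slimfield image and track generators
    with full ground truth, cell and nuclear-envelope segmentation,
    diffraction-limited focus detection and tracking by iterative Gaussian
    masking, stepwise-photobleaching stoichiometry with pairwise-difference
    periodicity analysis, pool copy-number deconvolution, diffusion-model
    fitting (MSD, CDF mixtures, Gamma mixtures, anomalous diffusion),
    trans-nuclear translocation geometry and FRAP turnover kinetics,
    cluster-diameter and packing-law estimation, Gaussian overlap-integral
    colocalization, IUPAC promoter-motif scanning on 3D genome models, and
    monomer-versus-cluster binding-model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    EBImage,
    Biostrings,
    pracma,
    minpack.lm,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
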