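Package: dphoresis
Title: Protein Diffusiophoresis in Dead-End Microfluidic Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Models and analysis tools for measuring protein diffusiophoresis
    in a dead-end microfluidic channel. Provides the similarity-variable
    boundary-value model of diffusiophoretic focusing in a transient salt
    gradient, a one-dimensional finite-volume simulator of coupled salt and
    protein transport, a synthetic fluorescence image-stack generator and the
    matching image-analysis pipeline (illumination flattening, Scharr channel
    detection, profile extraction, repeated Savitzky-Golay smoothing,
    normalization), and nonlinear least-squares fitting of concentration-peak
    profiles that extracts the protein diffusion coefficient, diffusiophoretic
    mobility, hydrodynamic radius and effective charge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    EBImage,
    jsonlite,
    Matrix,
    minpack.lm,
    signal,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
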