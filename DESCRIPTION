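Package: tomoreco
Title: Tomographic and Laminographic Reconstruction with Projection-Space
    Artifact Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Filtered back projection for parallel- and cone-beam computed
    tomography and laminography, including per-projection geometry (helical
    scans), projection pre-processing (flat/dark-field normalization, zinger
    removal, scintillator-spot masking and inpainting, half-acquisition
    stitching), propagation-based phase retrieval (transport-of-intensity and
    contrast-transfer-function inversion), Fourier-domain ring-artifact
    suppression on sinograms, non-local means denoising, rotation-axis
    estimation, parameter-sweep reconstruction, and an analytic phantom
    simulator for end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
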