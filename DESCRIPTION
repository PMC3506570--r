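Package: cardiotract
Title: Quantitative Diffusion Tensor Tractography of the Myocardium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative fiber tractography of the left ventricle
    from diffusion tensor imaging volumes. Streamlines are integrated through
    the primary eigenvector field with a fourth-order Runge-Kutta scheme,
    classified by whole-tract helix-angle statistics (minimum, median, maximum,
    mean), and summarized by transmural helix-angle curves, the tractographic
    coherence index (TCI), helix-angle histograms and the negative/positive
    variance ratio. Includes a synthetic left-ventricle phantom generator with
    known fiber architecture, a forward diffusion-weighted signal simulator,
    Hessian ridge-based orientation analysis for histology sections, and
    readers/writers for NIfTI volumes, FSL-style gradient tables and VTK
    legacy polydata tracts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
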