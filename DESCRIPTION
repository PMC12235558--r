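Package: cordparc
Title: Data-Driven Parcellation of Spinal Cord fMRI into Functional Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to extract and evaluate functional levels of the cervical
    spinal cord from resting-state fMRI. Implements physiological-noise
    denoising (CompCor, RETROICOR, cosine detrending, joint orthogonal
    projection with a 0.01 Hz high-pass), two network-extraction streams --
    hierarchical group independent component analysis (per-subject PCA,
    canonical-correlation group subspace, spatial ICA) and innovation-driven
    co-activation patterns built on Total Activation hemodynamic
    deconvolution -- and a full evaluation framework: Dice-based model-order
    stability under participant subsampling, maximum-weight matching of
    components to segmental levels, split-run temporal stability, and
    individual-level heatmaps. A synthetic spinal-cord fMRI generator with
    planted functional levels and full ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    yaml,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
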