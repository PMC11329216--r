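Package: amura
Title: Single-Shell Diffusion MRI Microstructure Indices with SVM
    Classification and Model Attribution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes ensemble-average-propagator restriction indices
    (return-to-origin, return-to-axis and return-to-plane probabilities)
    from single-shell diffusion MRI using spherical-harmonic expansions of
    the apparent diffusion coefficient with Laplace-Beltrami
    regularization, alongside their diffusion-tensor closed forms, mean
    diffusivity and fractional anisotropy. Provides multi-tensor phantom
    and cohort simulators with Rician noise, skeleton-masked ROI feature
    extraction, max-statistic permutation group tests, stratified
    cross-validated support vector machine classification, and KernelSHAP
    and LIME feature attributions with cross-method agreement summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    e1071,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
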