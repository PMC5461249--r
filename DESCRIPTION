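Package: bcilink
Title: Latent EEG-fMRI Linkage Discovery for Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering latent linkages between EEG and fMRI and
    for driving an EEG-only P300 speller with fMRI-like features estimated
    from those linkages. Includes Balloon-model hemodynamic simulation and
    blind deconvolution of BOLD into neuronal states via a square-root
    cubature Kalman filter and smoother, complex Morlet time-frequency
    tensorization of both modalities, non-iterative orthogonal Tucker
    (higher-order SVD) decomposition with a sequential update mode,
    higher-order partial least squares (HOPLS) tensor regression between the
    modalities, surrogate-data significance testing yielding sparse linkage
    models, a synthetic P300-speller session generator with a planted
    cross-modal linkage, and multivariate pattern decoders (linear SVM with
    recursive cluster elimination) for post-hoc and EEG-only letter decoding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
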