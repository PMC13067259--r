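Package: quantex
Title: Texture-Based Image Classification with Simulated Annealing and a
    Simulated Hybrid Quantum-Classical Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for classifying grayscale images by their texture
    statistics. Gray-level co-occurrence matrices (GLCMs) yield Haralick
    features (contrast, energy, correlation, homogeneity, entropy,
    dissimilarity) over a grid of pixel-pair distances and angles; a
    feature-specific simulated-annealing (FSSA) optimizer assigns each
    feature a continuous weight in [0,1] maximizing classification accuracy
    minus feature redundancy; and a hybrid quantum-classical classifier
    (amplitude-encoded inputs, a Hadamard-initialized hidden qubit register,
    controlled-rotation entanglement, exact Z-expectation readout through a
    tanh/sigmoid head) is trained by simulated annealing and evaluated with
    stratified k-fold cross-validation. A synthetic generator produces
    class-labelled Gaussian-random-field images with ordered texture
    statistics for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
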