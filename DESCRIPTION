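Package: pswarmnet
Title: Particle Swarm Selection of Neural Network Architectures and
    Hyperparameters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hybrid optimization of feedforward neural networks for
    classification and QSAR-style bioactivity regression.  A particle swarm
    optimizer with time-varying acceleration coefficients and inertia weight
    searches a bounded box of training hyperparameters (learning rate,
    dropout rate, momentum, decay) and per-hidden-layer neuron counts; each
    particle is scored by briefly training a from-scratch multilayer
    perceptron with mini-batch momentum gradient descent on a held-out
    validation split.  The personal-best solutions of the swarm are retrained
    in full and fused into a majority-vote ensemble.  Includes seeded
    synthetic data generators for pixel-like classification matrices and
    high-dimensional low-rank molecular-descriptor regression matrices, PCA
    preprocessing, a k-fold cross-validation experiment harness comparing the
    swarm-selected configurations against an equal-budget random baseline,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
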