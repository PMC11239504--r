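Package: dynmotifs
Title: Shared Dynamical Motifs in Multitask Recurrent Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trains continuous-time leaky recurrent neural networks on a
    suite of 15 cognitive tasks (delayed response, memory-guided response,
    reaction-timed response, perceptual decision-making and delayed match
    tasks) and analyzes the trained dynamics for reusable dynamical motifs.
    Provides a synthetic trial generator for all tasks, an Euler-discretized
    leaky RNN with backpropagation-through-time in C++, masked-loss Adam
    training with task interleaving, approximate fixed-point location and
    linear stability analysis, input-interpolation bifurcation detection,
    task-variance matrices with Ward clustering, cluster lesions, frozen-
    weight rule-input transfer learning, and state-space geometry summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    cluster,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
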