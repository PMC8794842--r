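Package: snnitl
Title: In-the-Loop Surrogate-Gradient Training of Spiking Networks on an
    Emulated Analog Substrate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains leaky integrate-and-fire spiking neural networks with
    surrogate-gradient backpropagation through time, where the forward pass
    runs on a simulated analog neuromorphic substrate exhibiting per-neuron
    parameter mismatch, intrinsic noise, quantized synaptic weights and
    sampled membrane readout. Recorded membrane traces and spikes are
    injected into an idealized differentiable computation graph through
    identity functions with surrogate derivatives, so that weight updates
    self-calibrate the heterogeneous substrate during learning. Includes
    spike-latency and event-stream encoders, task losses with sparsity and
    homeostatic regularizers, synthetic dataset generators, and experiment
    runners for self-calibration, sparsity, robustness and recurrence
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rhdf5,
    optparse,
    MASS
Config/testthat/edition: 3
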