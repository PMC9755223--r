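Package: sleepreplay
Title: Sleep Replay Consolidation for Continual Learning in Dense Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying catastrophic forgetting and its mitigation by an
    offline, noise-driven "sleep" phase in fully connected neural networks.
    Implements bias-free multilayer perceptrons trained by stochastic gradient
    descent with momentum, class-incremental and multi-modal task protocols,
    a rehearsal baseline with a task-weighted loss, and the sleep replay
    consolidation procedure: the trained network is viewed through spiking
    (Heaviside) semantics with data-derived per-layer scale factors, driven by
    Bernoulli noise whose rates are the running mean input intensities over
    all past training data, and updated by a local Hebbian rule that
    potentiates co-active synapses and depresses synapses onto active units
    from silent inputs. Includes a toy binary-patch task with controlled
    cross-task pixel overlap, a synthetic image generator, and replay
    diagnostics (class-correlation matrices, task-specific neuron
    identification, sleep firing-rate statistics, input-drive changes,
    weight-category histograms, and weight cosine similarity).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
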