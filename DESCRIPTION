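Package: synapkit
Title: Short-Term Synaptic Plasticity and Excitability Analysis for Patch-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-cell patch-clamp recordings of inhibitory
    synaptic transmission and neuronal firing. Implements a vesicle-depletion
    model of transmitter release (pool size N, release probability Pr, quantal
    size Q, constant replenishment) in deterministic and stochastic (binomial)
    modes; the Train and Elmqvist-Quastel cumulative-response estimators of
    release probability and readily releasable pool size; paired-pulse ratio,
    steady-state depression and recovery-from-depression quantification;
    scaled-template detection of miniature postsynaptic currents with
    biexponential kinetic characterisation; action-potential waveform feature
    extraction (threshold, amplitude, half-width, depolarisation and
    repolarisation rates, after-hyperpolarisation); and ground-truthed
    synthetic-trace generators for every supported recording protocol, so all
    analyses can be validated end to end without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
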