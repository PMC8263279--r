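Package: fnirsdbn
Title: Deep Belief Network Classification of Lateralized fNIRS Motor Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates trial-structured multichannel functional near-infrared
    spectroscopy (fNIRS) recordings of left- and right-arm motor execution and
    motor imagery, preprocesses them (zero-phase band-pass filtering, task
    epoch extraction, per-channel min-max normalization), and classifies
    left- versus right-arm tasks with a deep belief network built from two
    greedily pretrained restricted Boltzmann machines and a softmax output
    layer fine-tuned by conjugate gradients. Includes exact small-model
    enumeration oracles for the Boltzmann machine, per-subject and
    cross-subject (transfer) evaluation, and a reproducible end-to-end
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
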