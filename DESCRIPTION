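Package: riftsearch
Title: Frequency-Tagging Analysis of Guided Visual Search MEG Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of Rapid Invisible Frequency Tagging
    (RIFT) experiments on guided visual search. Provides a synthetic-data
    generator with known ground truth (tag-frequency carriers at 60 and 67 Hz,
    1/f background noise, broadband evoked onset response, blocked
    guided/unguided designs, gaze traces), behavioural summaries (d-prime,
    reaction-time descriptives, median splits), trial-averaged Hilbert-based
    coherence between sensors and a phase-matched reference, permutation-based
    selection of tagging-responsive sensors via a bias-corrected z-transformed
    coherence difference, single-trial Welch coherence with a general linear
    model (cope/varcope/t contrasts for target boosting and distractor
    suppression), cluster-based permutation inference over sensors and time,
    eye-movement control statistics, and DICS beamformer source-coherence
    mapping with truncated-SVD regularisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
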