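Package: m6Ascan
Title: Detection and Characterization of m6A-Containing RNA Sequence Windows
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds labeled 101-nt sequence windows around single-base
    N6-methyladenosine (m6A) sites, trains a hybrid convolutional /
    bidirectional-LSTM classifier to recognize m6A-containing sequences,
    and characterizes the trained model: first-layer filters are converted
    to position weight matrices (MEME minimal format output), gradient
    saliency maps attribute predictions to individual nucleotides,
    confidence tiers are calibrated to target specificities on validation
    negatives, and transcripts are tiled into bins to profile positional
    enrichment toward the 3' UTR. A synthetic-data generator plants DRACH
    motifs at known single-base positions so the whole pipeline is
    exercisable with ground truth and no external downloads. The neural
    network (convolutions, batch normalization, length-masked BLSTM, Adam,
    early stopping) is implemented in vectorized base R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
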