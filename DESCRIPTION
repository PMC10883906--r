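Package: crisproff
Title: CRISPR Cas-9 Off-Target Prediction with Recurrent Networks, Genetic
    Algorithm Model Selection and Integrated-Gradients Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts CRISPR Cas-9 off-target activity from sgRNA/target-DNA
    23-mer pairs. Implements the superposed (logical-OR) 4-channel and
    directional 5-channel one-hot pair encodings, a generic parameterized
    recurrent classifier (vanilla RNN, LSTM, GRU; stacked and bidirectional)
    trained with class-balanced bootstrap mini-batches, plain and elitist
    genetic-algorithm hyperparameter search optimizing validation AUPRC, and
    integrated-gradients interpretation with positional feature importance,
    seed/PAM region summaries, neuron-level layer attribution and activation
    heatmaps. Includes a synthetic benchmark generator with planted positional
    mismatch rules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
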