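Package: hayfever
Title: Attention-Based BiLSTM with Character Embeddings for Health-Related
    Tweet Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies short health-surveillance messages (e.g. hay fever
    related tweets) into relevance classes with a bidirectional LSTM,
    attention pooling and convolutional character embeddings that mitigate
    the out-of-vocabulary problem of user-generated text. Includes
    Twitter-aware preprocessing, vocabulary construction with
    out-of-vocabulary auditing, stratified k-fold cross-validation with
    early stopping, attention-weight visualization, and a synthetic noisy
    tweet generator for hermetic end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
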