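Package: cantm
Title: Classification-Aware Neural Topic Modelling for Short Health Texts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint classification and topic discovery for short
    health-disinformation texts with a stacked variational autoencoder.
    An M1 variational document model encodes each document into a Gaussian
    latent topic vector that both reconstructs the bag-of-words and feeds a
    softmax classifier; a class decoder ties one interpretable topic to each
    predefined category, and a stacked M2 model conditioned on the predicted
    label yields classification-aware topics that can be re-estimated on
    unlabelled corpora with the M1 weights frozen. Includes the
    multi-annotator curation pipeline (pairwise agreement, Cohen's kappa,
    leave-one-out annotator scoring, confidence filtering, majority and
    confidence label merging), corpus input/output and vectorisation,
    stratified cross-validation with accuracy, macro-F1 and variational
    perplexity, topic-word extraction from the decoder weight matrices, and a
    seeded synthetic corpus and annotator simulator for offline validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
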