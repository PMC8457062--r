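Package: beamchem
Title: Chemical Language Models with Beam-Search Design and Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for de novo molecular design with SMILES chemical language
    models (CLMs). Provides a SMILES tokenizer and vocabulary builder, a
    recurrent (LSTM) next-token language model trained by teacher forcing with
    per-epoch checkpointing and staged transfer learning, beam-search decoding
    that generates and intrinsically scores candidate molecules by the product
    of their token probabilities, temperature sampling as a stochastic
    baseline, an end-to-end design pipeline (staged fine-tuning, cross-epoch
    beam sampling, validity filtering, deduplication, novelty flagging and
    global ranking), and descriptor-based evaluation of design libraries
    (fraction of sp3 carbons, Morgan-type circular fingerprints, Tanimoto
    similarity and distance distributions). Includes generators for synthetic
    SMILES corpora and closed-form toy token-probability models used as exact
    oracles in tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
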