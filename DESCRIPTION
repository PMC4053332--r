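Package: turnsim
Title: Turn-Level Lexical and Syntactic Similarity in Dialogue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures lexical and syntactic repetition between speaker
    turns in conversation transcripts. Computes Dice-normalised
    matching-word-pair and complete-subtree similarity over a moving
    ten-turn window (five preceding turns by the same speaker, five by
    interlocutors), builds seeded randomised Chance-Other and
    Chance-Self counterpart conversations as a null baseline, and tests
    for convergence or divergence with a linear mixed model on
    per-person mean similarities, with lexical similarity as a
    covariate and Holm-adjusted real-vs-chance contrasts at each
    distance. Includes a probabilistic context-free grammar dialogue
    simulator with controllable cross-speaker priming strength and
    distance decay for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
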