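Package: ablm
Title: Masked Language Models and Probes for Natively Paired Antibody Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates natively paired heavy/light antibody repertoires
    (V(D)J recombination, correlated somatic hypermutation, heavy-to-light
    germline pairing preferences), builds paired, chain-shuffled and unpaired
    training corpora, trains small bidirectional transformer encoders with a
    masked-language-model objective, and probes what pairing contributes:
    region-wise cross-entropy, mutation masking against germline-reverted
    partner chains, cross-chain attention statistics, chain-sliced embeddings,
    and specificity classification with identity-clustered balanced datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
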