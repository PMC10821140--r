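Package: molcontrast
Title: Contrastive SMILES Representation Learning for Molecule Generation
    and Compound-Protein Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Maintainer", "molcontrast", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Self-supervised contrastive pre-training over enumerated
    (randomized) SMILES writings of the same molecule with an NT-Xent
    objective, and transfer of the learned token embedding into an
    autoregressive transformer decoder for de-novo molecule generation and
    into a dual-encoder compound-protein interaction classifier.  Includes
    the full distribution-learning evaluation layer (validity, uniqueness,
    novelty, success rate, internal diversity, Tanimoto similarity,
    QED/SAScore/LogP/TPSA profiling), dataset filters and splits, synthetic
    drug-like fixture corpora with a planted compound-protein signal, and a
    command-line interface.  Chemistry primitives are delegated to RDKit
    through a batched subprocess bridge; the neural stack (transformer
    encoder/decoder with hand-derived backpropagation, AdamW, early
    stopping) is implemented natively.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit on PATH as 'python'
Config/testthat/edition: 3
RoxygenNote: 7.3.3
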