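Package: mctsmol
Title: De Novo Molecular Generation by Monte Carlo Tree Search over SMILES
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates candidate molecules by Monte Carlo tree search (UCT)
    over the space of SMILES strings. A two-layer GRU character-level
    language model, trained on a SMILES corpus, supplies both the expansion
    prior and the rollout policy; rewards combine Crippen logP, the
    Ertl-Schuffenhauer synthetic accessibility score and a large-ring
    penalty into a bounded penalized-logP objective. Chemical validity and
    descriptors are computed by RDKit through a bundled Python worker.
    Includes a synthetic toy-corpus generator so the whole pipeline trains,
    searches and tests offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
SystemRequirements: Python (>= 3.8) with rdkit (including the SA_Score
    contrib) available on the PATH as 'python'.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
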