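Package: atrophyscan
Title: Detect Domain Atrophy in Profile-HMM Domain Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens profile-HMM domain annotations (HMMER3 per-domain
    tables or Pfam-style region tables) for partial protein domains that may
    represent domain atrophy, the loss of core structural elements from a
    domain. Computes N-terminal, C-terminal and within-domain atrophy scores
    (D - d)/L from HMM match-state and alignment coordinates, classifies
    candidate events into five architectural classes, applies a filter
    cascade that removes known failure modes (sequence fragments, low
    protein-existence evidence, tandem repeats, nested domains, same-clan
    adjacency, small models, overlapping hits), and summarises manual triage
    verdicts into class and failure-mode tallies with positive predictive
    value. Includes a synthetic annotated-proteome generator with planted
    ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tibble,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
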