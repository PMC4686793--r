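Package: adpio
Title: Inside-Outside Dynamic Programming over Strings and Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Algebraic dynamic programming engines with paired inside and
    outside recursions over strings and over unordered sets. Provides a
    symbolic grammar layer that mechanically derives the outside (backward)
    recursion of an inside decomposition scheme, together with concrete
    engines: a two-state CpG-island hidden Markov model (forward-backward and
    state posteriors), Needleman-Wunsch and Gotoh pairwise alignment with
    match posterior probabilities, a toy RNA secondary-structure grammar with
    partition function and base-pair probabilities, and exact Held-Karp /
    shortest-Hamiltonian-path dynamic programming with Boltzmann-ensemble
    adjacency and endpoint posteriors. Includes an application pipeline for
    gene-cluster analysis from homeodomain protein sequences and a synthetic
    serial-duplication cluster generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
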