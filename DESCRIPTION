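Package: dominet
Title: Dominance Hierarchy Inference from Direct and Indirect Agonistic
    Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers dominance hierarchies from win/loss interaction
    matrices using both direct encounters and transitivity-weighted
    indirect dominance pathways through the agonistic network. Computes
    pairwise dominance probabilities, finds the rank order maximizing the
    upper triangle of the probability matrix, detects nonlinear rank tiers,
    and quantifies dominance certainty at the dyadic, individual and group
    levels, with a diagnostic separating inferential from biological
    uncertainty. Includes a seeded simulator of agonistic data from a
    latent linear hierarchy and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
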