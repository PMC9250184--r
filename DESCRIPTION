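Package: methbn
Title: Consensus Bayesian Networks for Binary DNA Methylation States
Version: 0.1.0
Authors@R:
    person("methbn", "developers", email = "methbn@example.org", role = c("aut", "cre"))
Description: Learns consensus discrete Bayesian networks linking
    differentially methylated regions (DMRs) to a binary experimental
    condition. Methylation read counts are discretized at zero into binary
    methylation states, pairwise chi-square contingency tests build a
    blocklist of arcs with no evidence of dependence, and repeated batches
    of tabu searches maximising the Bayesian Dirichlet equivalent (BDe)
    score are combined by score-weighted arc-probability model averaging.
    Arcs classified as highly probable in every repetition form a weighted
    consensus network, from which the Markov blanket of the condition node
    is extracted. A synthetic-data module generates ground-truth networks
    and zero-inflated count matrices for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
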