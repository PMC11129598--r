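Package: ghosttrio
Title: Identifiability of Ghost Introgression in Species Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether introgression from an unsampled
    ("ghost") lineage can be told apart from introgression between sampled
    non-sister species in a three-species tree AB|C with a distant outgroup,
    under the multispecies coalescent with introgression (MSci). Provides
    closed-form gene-tree topology probabilities, site-pattern frequencies and
    the expected bias of HyDe-style introgression-fraction estimates; analytic
    piecewise-exponential densities of pairwise and joint coalescent times; a
    coalescent simulator for gene trees and multilocus sequence alignments; a
    site-pattern (HyDe-style) test with a block-jackknife variance estimate and
    Benjamini-Hochberg correction; a topology-count multinomial profile that
    exhibits the likelihood ridge making the introgression fraction
    unidentifiable from topologies alone; and a gene-tree-level full-likelihood
    fitter that distinguishes the three scenarios and recovers parameters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    lhs,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
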