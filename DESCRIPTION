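Package: scsnet
Title: Spectral Consensus Strategy for Large Network Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs large networks from high-dimensional categorical
    data with the Spectral Consensus Strategy: overlapping variable subsets
    are selected from the magnitude and sign of random-walk normalized
    Laplacian eigenvector elements, several structure learners (an ARACNE
    mutual-information filter, a hill climber maximising the BDeu score, and
    a random-classifier baseline) are run on every subset, each learner's
    local reconstructions are merged by an every-time intersection rule with
    majority-rule orientation, and the per-learner networks are integrated
    into a consensus by normalized-rank averaging with worst-rank imputation.
    Includes evaluation against a ground truth with a misorientation penalty,
    a pairwise Fisher's-exact co-presence baseline, and synthetic benchmark
    generators (random discrete Bayesian networks and planted co-presence
    block data).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
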