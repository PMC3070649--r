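Package: esmnet
Title: Elementary Signaling Modes and Component Essentiality in Signaling Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural analysis of signed, synergistic signaling networks.
    Boolean regulatory rules in disjunctive normal form are used to expand a
    signed network into an unambiguous all-activating representation with
    complementary and composite nodes. Node knockouts and constitutive
    activations are propagated as cascading disruptions, elementary signaling
    modes (minimal signal-transducing node sets) are enumerated, counted and
    minimized, and every component is scored with ESM-based, simple-path-based
    and classical centrality measures. A Boolean dynamics engine provides
    ground-truth essentiality for validation via ROC analysis, and a synthetic
    network generator supports testing at scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    igraph,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
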