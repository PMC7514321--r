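Package: causalcomp
Title: Causal Composition and Integrated Information of Discrete Dynamical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the causal composition of small discrete dynamical
    systems (Boolean networks, logic-gate circuits) given as node mechanisms or
    transition probability matrices. Computes state-dependent cause and effect
    repertoires with interventionist (do-operator) semantics and causal
    marginalization, irreducible cause/effect information (phi) of every
    mechanism via a minimum-information-partition search, and compositional
    system-level integrated information (big phi) under unidirectional system
    cuts, alongside Shannon-level baselines (entropy, Kullback-Leibler
    divergence, predictive and effective information). Includes samplers and
    exhaustive enumerators for deterministic, probabilistic, reversible and
    ergodic-reversible binary systems, time reversal, attractor analysis, and
    tidy sweep tables with ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
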