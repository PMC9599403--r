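Package: pznet
Title: Bipartite Phyto-Zooplankton Co-Occurrence Network Inference and Stability Analysis
Version: 0.1.0
Authors@R: person("Plankton", "Networks", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers signed bipartite co-occurrence networks between
    phytoplankton and zooplankton size fractions from community density
    tables using SparCC-style compositional correlations with permutation
    significance, and analyses their structure and stability: bipartite
    topology indices (links per species, clustering, quantitative linkage
    density, weighted connectance), degree-preserving Maslov-Sneppen null
    ensembles with one-sample t tests, robustness under guild-targeted
    random extinctions with secondary-extinction cascades, global-efficiency
    vulnerability, Zi/Pi module-role classification, preserved-module
    pairing across size fractions, module eigenvalue (eigengene) series,
    and Mantel tests linking node connectivity to environmental-factor
    significance. Includes a synthetic plankton-community generator with
    planted cross-guild associations and environmental coupling so the full
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
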