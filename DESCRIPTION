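Package: odocon
Title: Conservation Assessment of River Insect Assemblages
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assessing the conservation value of rivers from adult
    insect (Odonata) surveys. Computes land-cover heterogeneity via the
    Herfindahl-Hirschman index, Renyi diversity profiles, relative taxonomic
    distinctness, the Dragonfly Biotic Index, and the Croatian Conservation
    Odonatological Index; compares rivers with Kruskal-Wallis or one-way
    ANOVA routed through a Shapiro-Wilk normality gate, with compact letter
    displays; ordains assemblages by Bray-Curtis similarity with non-metric
    multidimensional scaling and UPGMA cluster overlays. A synthetic-data
    generator emulating a replicated multi-river survey design makes every
    stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
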