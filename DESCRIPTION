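Package: xlcaliper
Title: Cysteine Cross-Linking Caliper Analysis for Trimeric Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting bifunctional cysteine cross-linking
    experiments on C3-symmetric trimeric membrane receptors as molecular
    calipers. Converts between backbone (Ca-Ca) separations and the
    sulphhydryl-to-sulphhydryl span a cross-linker must bridge, predicts
    Western-blot monomer/dimer/trimer band fractions from the combinatorics
    of intratrimer cross-linking, filters/clusters structural model
    ensembles and extracts inter-subunit residue-pair distance
    distributions, performs anisotropic elastic-network normal-mode
    analysis of pair-distance changes, and quantifies gel lane densitometry
    including the percent-dimer statistic with one-way ANOVA and Bonferroni
    post-tests. Seeded synthetic-data generators (C3 helix bundles, scored
    model ensembles with planted structure, rendered gel images) provide
    ground-truthed inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    pracma,
    stats,
    utils,
    withr,
    zoo
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
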