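Package: CrystalContact
Title: Classify Biological Interfaces versus Crystal-Packing Contacts from B Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes true biological protein-protein interfaces from
    crystal-packing artifacts in X-ray structures using normalized
    B-factor (temperature-factor) features of interfacial atoms.
    Interfacial atoms are detected with beta contacts (distance cutoff,
    shared Voronoi facet, empty beta-skeleton forbidden region) followed
    by a local-contact filter; per-interface scores (sum of normalized B
    factors, per-residue averages, and a compound feature) are compared
    against the buried-surface-area baseline. Includes a single-feature
    threshold learner optimized by Matthews correlation, cross-dataset
    evaluation, Shrake-Rupley solvent-accessible surface areas, and a
    synthetic-structure generator with planted class structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
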