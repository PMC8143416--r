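Package: ptmbind
Title: Effects of Post-Translational Modifications on Protein-Protein
    Binding from MD-Derived Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis framework for quantifying how post-translational
    modifications (lysine acetylation and serine/threonine/tyrosine
    phosphorylation) affect protein-protein binding, starting from
    molecular-dynamics-derived energy tables. Provides structure-dataset
    curation rules, mapping of modification sites onto structure chains,
    MM/GBSA free-energy bookkeeping (binding free energy, ddG between
    modified and non-modified complexes, per-residue decomposition and
    interface classification, bound/unbound state contributions),
    conformational-change metrics (Kabsch superposition RMSD, RMSD-AUC
    differences, gromos clustering with representatives, periodic-image
    checks), conservation scoring of modification sites across orthologue
    alignments with taxonomy lowest-common-ancestor search, effect-size
    statistics, and a deterministic synthetic-data generator with ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    seqinr,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
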