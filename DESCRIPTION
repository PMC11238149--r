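Package: ahscan
Title: Amphipathic-Helix and Sequence-Feature Scanning for Septin Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate membrane-binding amphipathic helices in
    secondary-structure-annotated protein sequences using helical-wheel
    geometry, the mean hydrophobic moment, and a HeliQuest-style
    discriminant score; projects a reference septin GTPase domain onto
    query proteins by global pairwise alignment to delimit N- and
    C-terminal extensions; profiles the local isoelectric point along
    the N-terminal extension to flag polybasic regions; classifies
    reference-anchored catalytic residues (GAP-like arginine finger,
    switch-I threonine/serine); and aggregates per-protein feature
    calls into per-group conservation tables and set partitions.
    Includes deterministic synthetic-fixture generators for peptides
    and toy septin-like records with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
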