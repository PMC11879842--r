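Package: formayield
Title: Yield and Thermodynamics of Formate Assimilation Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based comparison of formate assimilation routes in
    Cupriavidus necator: stoichiometric model editing and flux balance
    analysis with growth-rate fixing and maintenance energetics, max-min
    driving force (MDF) thermodynamic analysis of the reductive glycine
    pathway versus the Calvin-Benson-Bassham cycle, exact net pathway
    stoichiometry and cofactor-cost accounting, and chemostat biomass-yield
    arithmetic and statistics. Reads and writes SBML Level 3 Version 1
    models and ships balanced synthetic fixtures so every stage runs
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
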