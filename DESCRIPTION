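Package: smalpomics
Title: Periprotein Lipidome Analysis of SMALP-Extracted Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for periprotein lipidomes captured in
    styrene-maleic-acid lipid particles (SMALPs) and profiled by
    HPLC-ESI-QToF mass spectrometry. Provides a theoretical lipid library
    (glycerophospholipids, yeast sphingolipids, ergosterol) with exact
    monoisotopic adduct masses; a filtering cascade that removes
    control-enriched background, salt clusters and redundant ion forms
    (isotopes, alternate adducts, dimers); Kendrick-style homolog grouping
    and accurate-mass identification; quantification by external standard
    curves and standard addition, class composition and
    sphingolipid/ergosterol ratio statistics; lipids-per-SMALP
    stoichiometry; and membrane-geometry estimates (SMALP lipid capacity,
    leaflet cross-section wedge integration, conformational lipid
    displacement). A synthetic-data generator with planted ground truth
    makes every stage testable without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
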