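Package: forceox
Title: Middle-Up LC-MS Analysis of Forced Methionine Oxidation in Monoclonal Antibodies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for middle-up characterization of IgG1 monoclonal
    antibodies under forced oxidation, aimed at biosimilarity assessment.
    Performs in-silico IdeS digestion and reduction into the LC, Fd' and
    Fc/2 subunits, enumerates proteoform mass libraries (glycans,
    pyroglutamate, C-terminal lysine, oxidation states), matches
    deconvoluted subunit masses at ppm tolerance, extracts per-species
    ion chromatograms for semiquantification of oxidation, compares
    reference product and biosimilar over a forced-degradation time
    course, and attributes oxidation to methionine sites by cross-antibody
    comparison. Includes a seeded synthetic LC-ESI-QTOF run generator
    driven by a per-site pseudo-first-order oxidation kinetics model, and
    a deterministic charge-series deconvolution of ESI envelopes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    mzR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
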