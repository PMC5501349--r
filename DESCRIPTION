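Package: middlemarks
Title: Middle-Down Mass Spectrometry of Combinatorial Histone Marks
    under Metabolic Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models GluC-cleaved histone N-terminal tail proteoforms carrying
    combinatorial methylation and acetylation marks, together with SILAC
    (heavy lysine/arginine) sequence labels and heavy-methyl (13CD3) marks
    deposited during metabolic labeling.  Matches deconvoluted ETD c/z
    fragment spectra against enumerated candidate proteoforms, filters
    identifications by site-determining fragment ions, splits co-isolated
    isobaric proteoform signal by fragment ion relative ratios (FIRR), and
    derives single-mark abundances, methylation turnover fractions, hybrid
    (partially heavy) methylation rankings and pairwise interplay scores.
    Includes a seed-deterministic synthetic spectra generator with ground
    truth for end-to-end validation, an MGF dialect for deconvoluted neutral
    masses, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
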