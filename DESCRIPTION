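Package: enzchar
Title: Enzyme-Inhibitor Characterization: IC50, Kinetics, Binding and
    Thermodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for characterizing small-molecule enzyme inhibitors
    from plate-reader assays: percent-inhibition and logit-method IC50
    estimation with fold-potency comparison against a reference inhibitor,
    Lineweaver-Burk kinetics with a Km(app)-vs-[I] secondary replot for the
    inhibition constant Ki and inhibition-mode classification, fluorescence
    static-quenching analysis for the association constant KA and binding-site
    number n, van't Hoff thermodynamic profiling (enthalpy, entropy, Gibbs
    energy) with non-covalent interaction-force classification, and circular
    dichroism secondary-structure composition comparison. Includes seeded
    synthetic-data generators matching each stage's statistical model so every
    fitter is testable by parameter recovery, plus CSV readers and a
    JSON compound report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
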