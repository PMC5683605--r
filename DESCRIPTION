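Package: cpdquant
Title: Quantitative Peptidomics Profiling of Carboxypeptidase Substrate Specificity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the substrate specificity of
    metallocarboxypeptidases (in particular the two active domains of human
    carboxypeptidase D) by quantitative peptidomics. Implements in-silico
    tryptic digestion of protein libraries, monoisotopic mass and charge
    bookkeeping for TMAB (4-trimethylammoniumbutyrate) 5-plex isotopic
    labeling, detection and censored ratio quantification of labeled peak
    sets in centroided MS1 peak lists, dose-dependent substrate/product
    classification with P1'/P1 preference profiling, Michaelis-Menten
    kinetics fitting with kcat/Km efficiency and pH-activity summaries,
    a geometric docking-pose correctness filter, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
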