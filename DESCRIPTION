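Package: hismet
Title: Detection, Localization and Quantification of N-Terminal Histidine
    Methylation from Proteomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying N-terminal histidine methylation of secreted
    proteins (such as lytic polysaccharide monooxygenases) by mass
    spectrometry. Provides monoisotopic mass arithmetic for modified tryptic
    peptides, fragment and immonium ion calculation, in-silico Trypsin/P and
    LysC digestion, isotope envelope prediction, diagnostic-ion assisted
    localization of His1 methylation in MS/MS spectra, parallel reaction
    monitoring (PRM) quantification with a knockout-screen decision rule,
    methylation stoichiometry from MS1 precursor isotope areas,
    permutation-FDR differential protein abundance with left-censored
    imputation, and a staged candidate funnel for shortlisting putative
    methyltransferases. A synthetic-data module generates every input with
    recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
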