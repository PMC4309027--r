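Package: phosphoscan
Title: Phosphopeptide Identification from CID Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("phosphoscan", "developers", role = c("aut", "cre"),
    email = "phosphoscan@example.org")
Description: A complete pipeline for identifying phosphopeptides and
    localizing phosphorylation sites from collision-induced dissociation
    (CID) LC-MS/MS spectra. Builds target/decoy/composite peptide
    databases from protein FASTA by in silico tryptic digestion with
    variable serine/threonine phosphorylation and fixed cysteine
    carbamidomethylation; reads and merges Sequest-style dta spectra;
    prescreens spectra for the diagnostic H3PO4 neutral-loss signal;
    scores candidate phosphosite isomers against experimental spectra
    with a sigmoid intensity-weighted match score; validates target hits
    with decoy-derived empirical p-values under Bonferroni correction;
    and computes detection/localization performance metrics. A
    ground-truthed synthetic CID spectrum generator supports end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
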