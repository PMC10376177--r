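Package: xlinkxic
Title: Targeted Detection of Covalent Peptide Crosslinks in LC-MS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for the targeted search of covalently crosslinked tryptic
    peptides, such as the Met-Tyr-Trp adduct of catalase-peroxidases, in
    centroided LC-MS runs. Provides in-silico tryptic digestion, monoisotopic
    and average mass computation with fixed and variable modifications,
    enumeration of site-covering crosslink candidates with the loss of two
    hydrogen atoms per covalent bond, charge-state ion-form calculation,
    extracted-ion-chromatogram coelution detection, and charge deconvolution
    to neutral monoisotopic mass. A seeded synthetic-data module generates
    ground-truthed LC-MS runs (averagine isotope envelopes, Gaussian elution,
    noise), linear absorbance kinetics traces, and sigmoidal thermal-unfolding
    curves; companion routines compute specific enzymatic activities from
    absorbance slopes via extinction coefficients and extract melting
    temperatures and onsets from fluorescence-ratio curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
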