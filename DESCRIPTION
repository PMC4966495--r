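Package: adcdar
Title: Multidimensional Characterization and Drug-to-Antibody Ratio
    Quantitation of Cysteine-Conjugated Antibody-Drug Conjugates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the in-silico characterization of cysteine-conjugated
    antibody-drug conjugates (ADCs) by heart-cutting two-dimensional liquid
    chromatography with mass spectrometric detection. Enumerates the
    positional isomers generated by partial inter-chain disulfide reduction
    of an IgG1, predicts the covalent sub-unit masses each isomer dissociates
    into under denaturing reversed-phase conditions, integrates hydrophobic
    interaction chromatography (HIC) peak profiles to compute drug-to-antibody
    ratios (DAR) with replicate statistics, deconvolves continuum
    electrospray charge-state envelopes to neutral average masses, and
    matches observed sub-unit masses against the isomer signature library.
    A synthetic-data module generates HIC chromatograms, heart-cut fractions
    and continuum ESI spectra with known ground truth so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
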