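Package: glycolib
Title: Open Spectral Library Search for Intact N-Linked Glycopeptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open (precursor-tolerant) spectral library search engine for
    the identification of intact N-linked glycopeptides from HCD MS/MS
    spectra. Deglycopeptide identifications and their spectra are turned into
    an optimized consensus library (theoretical-spectrum blending, theoretical
    m/z substitution, trimannosyl-core Y0-Y5 ion injection, J encoding of
    glycosylated Asn); query spectra are screened for the HexNAc diagnostic
    oxonium ion, deisotoped, stripped of oxonium ions and density-capped;
    candidate (library spectrum, glycan composition) pairs are selected by
    precursor mass and scored with the product of a spectral dot product and
    a binomial probability score; false discovery rates are controlled with
    sequon-preserving reversed decoy spectra. A deterministic synthetic
    fixture generator provides deglycopeptide identifications, replicate
    library spectra and intact glycopeptide query spectra with known ground
    truth so the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
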