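Package: QlinkerQuant
Title: Quantitative Crosslinking Mass Spectrometry with Isobaric
    Qlinker Reporter Ions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for 2-plex isobaric quantitative crosslinking mass
    spectrometry (qCLMS) with amine-reactive Qlinker reagents. Extracts
    the 126/127 reporter-ion intensities from identified MS2 spectra,
    corrects them for isotope impurity through a 2x2 purity matrix,
    computes per-spectrum log2 abundance ratios and aggregates them per
    crosslink or monolink site. Includes parsers for crosslink search
    results, b/y fragment annotation with the four-consecutive-ion
    spectrum validation rule, mixing-series and label-swap concordance
    analyses, a reporter-interference scan, mapping of quantified sites
    onto 3D structures (C-alpha distance restraints and salt-bridge
    detection), and a seeded synthetic-data generator producing spectra,
    identifications and ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    mzR,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Proteomics, MassSpectrometry, Software
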