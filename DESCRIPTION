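Package: xlscout
Title: Cross-Linking Mass Spectrometry Search and Subunit Stoichiometry for
    Photosystem Supercomplexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identification of chemically cross-linked peptide pairs from
    tandem mass spectra using an isotope-coded DSS (d0/d12) cross-linker, a
    Poisson-based E-value score and a two-step (targeted database then whole
    proteome) validation search; downstream mapping of cross-links to subunit
    adjacency graphs and C-alpha distance restraints on structural models; and
    quantification of subunit stoichiometry from uniform 14C gel densitometry
    via carbon-number normalization, comigration calibration and composite
    band partitioning. Includes a synthetic-data generator that emulates
    tryptic cross-linked spectra and gel band tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    mzR,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
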