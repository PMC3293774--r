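Package: furdock
Title: Template-Analogy Modelling of FUR-Family Regulator-DNA Complexes
    and Multimer Spacing Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building three-dimensional models of winged
    helix-turn-helix (wHTH) transcription-factor dimers bound to DNA by
    structural analogy with experimental protein-DNA complexes, and for
    exploring multimeric ("dimer of dimers" and higher) arrangements by
    sliding dimer copies along ideal B-DNA in one-base-pair helical
    increments.  Includes a fixed-width PDB reader/writer, rigid-body
    superposition (Kabsch), an ideal B-DNA builder with screw-transform
    algebra, base threading onto a fixed phosphodiester backbone,
    deterministic Shrake-Rupley solvent-accessible surface areas, the
    contact-surface statistic CS = (SASA_rec + SASA_lig - SASA_cplx)/2,
    steric-clash scoring, per-nucleotide buried-surface DNA footprints,
    spacing-scan classification (clash/contact/separated), transcriptional
    switch reports for divergent promoters, and sigma-70 promoter motif
    scanning (-10/-35 boxes, AT-only runs, GATAAT repeat arrays, 7-1-7
    inverted repeats).  Synthetic fixture generators make every analysis
    reproducible without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    generics,
    tibble,
    dplyr,
    purrr,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    Biostrings,
    bio3d,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
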