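Package: ribocodon
Title: Differential Ribosome Codon Reading with a Shift-Based Empirical Null
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Codon-level analysis of ribosome profiling and nascent proteome
    data. Computes gene-level-normalized A-site (and P-site) codon occupancy
    from footprint alignments in transcript coordinates, differential ribosome
    codon reading between conditions, and per-codon significance against an
    empirical null built from signals at 1-nucleotide out-of-frame shifts.
    Computes per-transcript codon usage, percent deviation from the
    transcriptome-average reference, and VAA codon-set aggregates, and
    correlates codon usage deviation with nascent-proteome fold changes via
    decile ranks and rank-sum tests. Includes a synthetic-data generator with
    known ground truth (codon-dependent dwell, frame noise, replicate
    structure, codon-usage-driven synthesis effects) for calibration and
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    nortest,
    stats,
    utils
Suggests:
    Rsamtools,
    yaml,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
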