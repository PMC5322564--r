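Package: editscan
Title: Quantification of CRISPR Editing Outcomes from Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies Cas9 editing outcomes from paired-end amplicon deep
    sequencing. Paired reads are merged into observed sequences by 3'-overlap
    stitching with quality-based consensus, validated against wild-type
    terminal anchors, and compared with the wild-type amplicon by two-sided
    inward scanning: forward and reverse breakpoints are placed where the
    observed sequence first differs from wild type by at least two consecutive
    mismatches, defining per-molecule deletion and insertion regions. Sample
    level summaries include length-based indel efficiency, per-position edited
    fractions, deletion and insertion length distributions, ranked editing
    pattern tables, and a deletion pileup. A ground-truthed read simulator
    supports end-to-end validation, and closed-form helpers cover SURVEYOR
    densitometry indel estimation and caliper tumour volume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
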