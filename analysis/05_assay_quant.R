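#!/usr/bin/env Rscript
# Closed-form assay quantifications on example inputs: SURVEYOR
# densitometry indel percentages for a dilution-style series of band
# intensities, and caliper tumour volumes. Writes results/assays/.

suppressPackageStartupMessages(library(editscan))

out_dir <- "results/assays"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# band intensity series: increasing cleaved fraction at fixed total signal
bands <- data.frame(
  a = c(100, 90, 75, 50, 25, 0),
  b = c(0, 6, 15, 30, 45, 60),
  c = c(0, 4, 10, 20, 30, 40)
)
bands$indel_pct <- with(bands, surveyor_indel_percent(a, b, c))
write.table(bands, file.path(out_dir, "surveyor.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("SURVEYOR indel % by cleaved fraction:")
print(bands, digits = 4)

# caliper measurements (mm) over a mock ten-day course
tumours <- data.frame(
  day = c(0, 2, 4, 6, 8, 10),
  d_short = c(4.0, 4.2, 4.6, 5.1, 5.8, 6.4),
  d_long = c(5.0, 5.4, 6.0, 6.9, 7.7, 8.6)
)
tumours$volume_mm3 <- with(tumours, tumour_volume(d_short, d_long))
write.table(tumours, file.path(out_dir, "tumour_volume.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("tumour volumes (mm^3):")
print(tumours, digits = 4)
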