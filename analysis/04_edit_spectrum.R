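#!/usr/bin/env Rscript
# Aggregate per-read calls into sample editing profiles: indel efficiency,
# per-position edited fractions, deletion/insertion length distributions,
# and the cross-sample table of the 20 most frequent editing patterns.
# Writes tables under results/spectrum/ and (if ggplot2 is available) a
# three-panel summary figure per sample.

suppressPackageStartupMessages(library(editscan))

sim_dir <- "results/sim"
call_dir <- "results/calls"
out_dir <- "results/spectrum"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

samples <- read.delim(file.path(sim_dir, "samples.tsv"))
eff <- list()
all_calls <- list()

for (sid in samples$sample_id) {
  ref <- read_amplicon_reference(file.path(sim_dir, paste0(sid, "_ref.fasta")),
                                 file.path(sim_dir, paste0(sid, "_ref.tsv")))
  calls <- read.delim(file.path(call_dir, paste0(sid, "_calls.tsv")),
                      stringsAsFactors = FALSE)
  calls$inserted_sequence[is.na(calls$inserted_sequence)] <- ""
  prof <- editing_profile(calls, ref, sample_id = sid)
  write_profile(prof, file.path(out_dir, sid))
  eff[[sid]] <- data.frame(sample_id = sid,
                           truth_edited_fraction = samples$edited_fraction[
                             samples$sample_id == sid],
                           indel_efficiency_pct = prof$indel_efficiency,
                           n_sequences = prof$n_sequences)
  calls$sample_id <- sid
  all_calls[[sid]] <- calls
  message(sprintf("%-10s efficiency %.2f%% over %d sequences",
                  sid, prof$indel_efficiency, prof$n_sequences))

  if (requireNamespace("ggplot2", quietly = TRUE)) {
    plots <- plot_editing_profile(prof)
    pdf(file.path(out_dir, paste0(sid, "_summary.pdf")), width = 10, height = 3)
    print(plots$per_position); print(plots$deletions); print(plots$insertions)
    dev.off()
  }
}

eff <- do.call(rbind, eff)
write.table(eff, file.path(out_dir, "indel_efficiency.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# supplementary-style cross-sample pattern table: top 20 patterns with
# per-sample counts and rendered alignments
pooled <- do.call(rbind, all_calls)
ref <- read_amplicon_reference(
  file.path(sim_dir, paste0(samples$sample_id[1], "_ref.fasta")),
  file.path(sim_dir, paste0(samples$sample_id[1], "_ref.tsv")))
top <- top_patterns(pooled, ref, n_top = 20L)
write.table(top, file.path(out_dir, "top20_patterns.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote ", out_dir)
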