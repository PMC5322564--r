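# editscan

Quantification of CRISPR/Cas9 editing outcomes from paired-end amplicon
deep sequencing, built around a two-sided breakpoint-scanning caller, with
a ground-truthed read simulator for end-to-end validation.

## The problem

After Cas9 cuts a genomic target, repair by non-homologous end joining
leaves a spectrum of insertions and deletions (indels) around the cut
site. Deep sequencing of a PCR amplicon spanning the target captures this
spectrum: each read pair is one molecule, and the analysis must decide,
molecule by molecule, what was deleted and what was inserted relative to
the wild-type sequence. `editscan` implements that analysis for the common
MiSeq design (2×150 bp reads over a ~200 bp amplicon, here a TP53 target
site), together with the sample-level summaries used to report editing:
length-based indel efficiency, per-position edited fractions, indel length
distributions and ranked tables of recurrent editing patterns.

## The method

**Stitching.** Each read pair is merged into an "observed sequence": the
reverse mate is reverse-complemented and joined to the forward mate at the
3′ overlap (≥ 15 bp; the candidate overlap with the fewest mismatches
wins, ties to the longest; discordant bases resolve to the higher Phred
score). An observed sequence is analysed only if both of its ends — each a
mate's 5′ end — retain 40 bp of wild-type sequence (the *anchors*).

**Breakpoint calling.** The observed sequence *S* and the wild-type
sequence *W* are compared without gaps, starting from both ends and moving
inward. The forward breakpoint *f* is the smallest offset at which *S* and
*W* (left-aligned) differ at two consecutive positions; the reverse
breakpoint *r* is the mirror-image offset from the right (right-aligned),
expressed in wild-type coordinates. Isolated single mismatches —
sequencing errors — never trigger a breakpoint. Then

- deletion = *W*[*f* : *r*], the wild-type sequence between the breakpoints;
- insertion = *S*[*f* : *r*′], the observed sequence between them
  (*r*′ = *r* − (|*W*| − |*S*|));

so that |*S*| − |*W*| = |insertion| − |deletion| for every call. Because
the scans tolerate isolated mismatches, chance matches inside the
disrupted region can push the breakpoints past each other; such crossings
are reconciled deterministically (the overhang is split evenly and the net
region keeps length \||*S*| − |*W*|\|), and calls whose deletion *and*
insertion both exceed 25 bp are flagged as likely artifacts of the caller
meeting a stretch of poor sequence. All coordinates are 0-based half-open.

**Summaries.** Indel efficiency is the percentage of anchor-passing
sequences whose length differs from wild type (length-neutral edits, with
equal insertion and deletion lengths, are invisible to it by design).
Per-position edited fractions count, at each reference base, deletions
spanning it or insertions adjacent to it. Deletion/insertion length
histograms and a ranked pattern table (with per-sample counts and rendered
alignments) complete the profile.

**Auxiliary closed forms.** SURVEYOR densitometry indel percentage,
100·(1 − √(1 − (b+c)/(a+b+c))) for band intensities a (uncut), b, c
(cleaved), and caliper tumour volume (d²short × dlong)/2.

## Worked example

Simulate a sample in which 60% of molecules carry a 6 bp deletion at the
cut site, sequence it error-free, and run the pipeline:

```r
library(editscan)

cfg <- simulation_config(
  n_molecules = 2000, edited_fraction = 0.6,
  deletion_length_distribution = list(name = "fixed", length = 6),
  insertion_probability = 0, substitution_error_rate = 0, rng_seed = 11)
sample <- simulate_sample(cfg)
res <- run_pipeline(sample$pairs, cfg$reference)
res$profile
#> <editing_profile> sample sample1
#>   anchor-passing sequences: 2000
#>   indel efficiency: 59.35%
#>   peak edited fraction: 0.594 at position 99
```

The realised edited fraction in this draw is 59.35% (1187/2000 molecules),
and the pipeline recovers it exactly: every edited molecule is called with
a 6 bp deletion, and the per-position edited fraction peaks at position 99,
adjacent to the configured cut site (100). The breakpoint primitives are
directly inspectable:

```r
forward_breakpoint("AAAACCAA", "AAAAAAAA")   # 4
reverse_breakpoint("AAAACCAA", "AAAAAAAA")   # 6  -> deletion [4,6), insertion "CC"
forward_breakpoint("AACAAAAA", "AAAAAAAA")   # NA: isolated mismatch tolerated
surveyor_indel_percent(a = 1, b = 1, c = 1)  # 42.26497
```

## The analysis workflow

`analysis/` holds the numbered study drivers, each a thin script over the
package that writes its tables under `results/`:

1. `01_simulate.R` — eight samples (four vehicle, four induced) of 4,000
   read pairs each, with ground truth.
2. `02_stitch.R` — stitching + anchor accounting per sample.
3. `03_call_indels.R` — per-read breakpoint/indel calls, checked against
   the simulation truth.
4. `04_edit_spectrum.R` — editing profiles, efficiency table, and the
   cross-sample top-20 pattern table.
5. `05_assay_quant.R` — SURVEYOR and tumour-volume example tables.

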