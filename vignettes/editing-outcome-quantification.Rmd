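---
title: "Quantifying CRISPR editing outcomes by two-sided breakpoint scanning"
author: "editscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRISPR editing outcomes by two-sided breakpoint scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscan)
```

## The model

A Cas9-targeted amplicon sequenced with overlapping paired-end reads
yields, per read pair, one *observed sequence*: a reconstruction of a
single molecule of the edited locus. `editscan`'s model of an observed
sequence is deliberately minimal — a molecule is wild type, or it carries
one contiguous deletion and/or one insertion at a single junction near the
cut site. That is the repair spectrum non-homologous end joining produces
at a single blunt cut, and it is the structure the caller reports: one
deletion region (in wild-type coordinates) and one insertion region (in
observed-sequence coordinates) per molecule.

The caller is *ungapped by construction*. The observed sequence is
compared with wild type positionally, from both ends moving inward, and a
breakpoint is placed where the two first differ by at least two
consecutive mismatches. The two-consecutive rule is the method's entire
error model: an isolated substitution — the dominant sequencing-error mode
after stitching — can never move a breakpoint, while a true indel shifts
the register of every downstream base and produces dense mismatches at
once. The price of gap-freedom is that edits are localised only up to the
homology structure of the locus (see *Boundary ambiguity* below), and that
a length-neutral edit whose insertion resembles its deletion can be
invisible. Both are properties of the method, not defects of the
implementation, and both are measured by this package's tests.

## Pipeline stages and their parameters

**Stitching** (`stitch_pairs`). Mates must overlap by at least
`min_overlap = 15` bp in their 3′ ends. Among admissible overlaps the one
with the fewest mismatches wins, ties to the longest; the winner must have
a mismatch fraction at most `max_overlap_mismatch_frac = 0.1`. Mismatch
tolerance is allowed because real reads carry errors: exact-overlap
stitching would selectively discard error-bearing molecules and bias the
spectrum. Under this tie-break the winner is always unique (overlap
lengths are distinct), so the ambiguous-overlap rejection path is
defensive only. At discordant overlap positions the base with the higher
Phred score is kept, ties to the forward read; `N` counts as a mismatch
everywhere in the package.

**Anchor filter** (`check_wildtype_anchor`). An observed sequence enters
calling only if its first and last `anchor_len = 40` bases match the
corresponding wild-type termini with at most `max_anchor_mismatches = 0`
mismatches. The anchor is checked on the stitched sequence (each end is a
mate's 5′ end, so this is equivalent to a per-mate check for full-length
mates). Zero tolerance is the strict reading of "wild-type ends"; it is
configurable because deep-coverage applications may prefer to keep
anchor-eroded reads.

**Breakpoint calling** (`call_indel`). Forward breakpoint `f`: smallest
0-based offset at which observed and wild type, left-aligned, mismatch at
two consecutive positions. Reverse breakpoint `r`: the mirror scan from
the right, reported half-open in wild-type coordinates. Deletion =
wild type `[f, r)`; insertion = observed `[f, r′)` with
`r′ = r - (len(wt) - len(obs))`. Scanning stops at the shorter of the two
sequences. One-sided outcomes (only one scan fires) cannot define regions
and are classified wild-type-like with a machine-readable note.

**Boundary ambiguity and reconciliation.** Because the scans tolerate
isolated mismatches, each breakpoint can overshoot the true junction by a
few bases when flanking sequence happens to match across the indel — the
same ambiguity by which a deletion in a repeat has no unique placement.
The two overshoots are independent, so the breakpoints can land *past*
each other, which would imply a negative-length region. Numerically this
is the common case, not a corner: for a 6 bp deletion in random context
the raw breakpoints cross in roughly half of error-free molecules. The
package reconciles every crossing deterministically: the overhang
`f - min(r, r′)` is split evenly between the two breakpoints, the region
on the net-indel side keeps exactly `|len(obs) - len(wt)|` bases and the
other region becomes empty. The reconciled call remains consistent with
both scans (neither flank contains a double mismatch in its frame), always
satisfies the length identity `len(obs) - len(wt) = ins - del`, and in
validation recovers the true indel length exactly, with the interval
placed within a few bases of truth (the even split keeps the placement
unbiased). Reconciled calls are annotated `boundary_reconciled`.

**Artifact flagging.** A distinct failure mode arises when a scan stops
far from the cut site on a stretch of poor sequence — typically the
low-quality 3′ tail of reverse reads — producing a long deletion paired
with a long insertion. Calls whose deletion *and* insertion both reach
`artifact_min_len = 25` bp are flagged `artifact`; they are excluded from
per-position fractions and length histograms but retained in pattern
tables, where long insertions are rendered as a bracketed length rather
than literal sequence. The threshold is a display/QC choice: genuine
single-junction repair events of that joint size are vanishingly rare in
this design, while the artifact signature is exactly the long/long pair.

**Summaries** (`editing_profile`). Indel efficiency is
`100 × (# anchor-passing sequences with length ≠ wild type) / (# anchor-passing sequences)`;
a call's length difference is computed as `len(obs) - len(wt)`, so
artifact-flagged calls still contribute their (reliable) length change
even though their regions are suspect. The per-position edited fraction
uses as denominator *all* anchor-passing, non-artifact sequences —
"fraction of sequences" read literally — and marks, per edited sequence,
every deleted base plus the two bases flanking an insertion junction
(configurably one-sided). Length histograms include a mass at length 0
(sequences with no deletion, resp. no insertion), so each distribution
sums to 1, and a sequence with both an insertion and a deletion
contributes to both. Pattern ranking breaks count ties by smaller deletion
start, then lexicographic insertion, making tables reproducible.

## The simulator as study design

The synthetic module generates the conditions the analysis is validated
under, with defaults fixed once:

- **Locus**: a fixed 200 bp amplicon whose terminal 20-mers are the true
  TP53 target-region primer pair and whose interior is synthetic, with a
  20 bp protospacer at `[83,103)` and the blunt cut at 100, 3 bp from the
  NGG PAM. A synthetic interior keeps the package self-contained; the
  frame (primer-flanked amplicon, centred cut) matches the sequenced
  design.
- **Reads**: 2×150 bp, so a full-length molecule gives 100 bp of mutual
  overlap, comfortably above the 15 bp floor.
- **Depth**: 10,000 pairs per sample by default (the experiment's per-
  sample depths are not published; this is a typical MiSeq amplicon
  allocation). The bundled eight-sample analysis uses 4,000 to keep the
  worked example fast.
- **Editing model**: `edited_fraction = 0.6` by default (a strong-editing
  condition); deletion lengths geometric (`p = 0.3`, mean ≈ 3.3 bp),
  placed uniformly over positions whose closed interval contains the cut
  site and never invading the 40 bp anchors (inadmissible draws are
  redrawn, capped); insertions with probability 0.2, geometric lengths
  (`p = 0.5`), random bases at the deletion junction. These reproduce the
  qualitative spectrum of NHEJ at a single cut: short deletions clustered
  on the cut site, rarer short insertions.
- **Errors**: uniform per-base substitutions at `0.001` (typical MiSeq
  scale), substitutions only. Read-level indel errors are excluded on
  purpose: the caller is ungapped and its error robustness device is the
  two-consecutive-mismatch rule, which the substitution model exercises
  directly. A `nonadjacent_errors` switch thins errors so no two are
  adjacent — a validation device that makes "only isolated errors" a
  guarantee rather than a high-probability event.
- **Qualities**: Phred 37 flat, with a linear decline to Phred 20 over the
  last 50 bases of the reverse read, emulating the low-quality reverse
  tails that produce the long/long artifact and exercising the
  quality-based consensus rule at stitch time.

What the simulator does *not* model — PCR chimeras and recurrent
polymerase slippage, adapter read-through, context-dependent error rates,
microhomology-biased repair outcomes — bounds what passing tests show:
they demonstrate that the implementation is faithful to the stated rules
and recovers known truth under those rules, not that the rules themselves
are optimal for any given real library.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open everywhere (BED convention), chosen so
  deletion length is `end - start` and intervals concatenate without ±1
  bookkeeping.
- Scanning stops at `min(len(obs), len(wt)) - 1`; the shorter sequence is
  never padded.
- Empty inputs error; a stitched sequence shorter than two anchors fails
  the anchor check with reason `too_short`; zero anchor-passing sequences
  make efficiency undefined (an error, not 0).
- Determinism: every random draw flows from `rng_seed` via isolated seed
  scopes (`withr::with_seed`), so identical configurations produce
  byte-identical FASTQ, call tables and profiles.
- The simulator resolves a degenerate edit draw (empty deletion, no
  insertion) by recording the molecule as unedited, keeping the truth
  flag equivalent to "the molecule differs from wild type".

## Validation results computed by this package

The test suite and `scripts/acceptance.R` compute (not assert from
constants): exact agreement of both scans with a brute-force oracle on
1,000 random sequence pairs; zero false edited calls on 10,000 molecules
carrying isolated substitutions at 0.003/base; recovery of a simulated
60% editing rate within binomial error and of a fixed 6 bp deletion length
in ≥ 99% of edited calls, with the per-position fraction maximal at the
cut site; exact reconstruction of error-free molecules by stitching with
rejection below the 15 bp overlap floor; the length identity on every
non-artifact call; the SURVEYOR closed forms (0% and 100% limits, scale
invariance, round-trip inversion); and byte-identical reruns.

## Known limitations

- Only single-junction events are represented: two separated deletions on
  one molecule merge into one call spanning both.
- Deletion intervals are reported without left/right normalisation in
  repeats; identical molecules always get identical calls, but the
  interval is one representative of its homology class.
- Length-neutral edits are invisible to the efficiency statistic by
  definition, and near-identical substitution-like edits (equal-length
  insertion/deletion differing at one position) can be called wild-type-
  like; both are inherent to the published statistic and the ungapped
  scan.
- The anchor filter discards molecules with errors in their terminal
  40 bp (~8% at the default error rate), which slightly biases depth but
  not composition; the run report accounts for every discarded read.
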