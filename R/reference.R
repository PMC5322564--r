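# Wild-type amplicon reference: the coordinate frame all breakpoints,
# deletion intervals and per-position statistics are expressed in.
# All reference coordinates in this package are 0-based, half-open (BED
# convention).

#' Construct a wild-type amplicon reference
#'
#' Bundles the wild-type amplicon sequence with the Cas9 cut site and the
#' sgRNA protospacer interval. Every breakpoint and deletion interval
#' reported by the package is expressed in this frame, 0-based half-open.
#'
#' @param sequence Wild-type amplicon sequence (single character string over
#'   `A`, `C`, `G`, `T`, `N`).
#' @param cut_site 0-based offset of the expected Cas9 blunt cut (the
#'   position of the first reference base 3' of the scissile bond). Must lie
#'   within 10 bp of the protospacer interval.
#' @param guide_start,guide_end 0-based half-open interval of the sgRNA
#'   protospacer on the amplicon.
#' @param name Identifier for the amplicon.
#'
#' @return An object of class `amplicon_reference`: a list with elements
#'   `name`, `sequence`, `cut_site`, `guide_start`, `guide_end`.
#' @examples
#' ref <- tp53_amplicon()
#' nchar(ref$sequence)
#' @export
amplicon_reference <- function(sequence, cut_site, guide_start, guide_end,
                               name = "amplicon") {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    stop("non-nucleotide character '", substr(sequence, bad, bad),
         "' at position ", bad, " of reference sequence")
  }
  len <- nchar(sequence)
  cut_site <- as.integer(cut_site)
  guide_start <- as.integer(guide_start)
  guide_end <- as.integer(guide_end)
  if (guide_start < 0L || guide_end > len || guide_start >= guide_end) {
    stop("guide interval [", guide_start, ",", guide_end,
         ") is not a valid interval within the amplicon")
  }
  if (cut_site < guide_start - 10L || cut_site > guide_end + 10L) {
    stop("cut_site ", cut_site, " lies more than 10 bp outside the guide interval")
  }
  structure(
    list(name = name, sequence = sequence, cut_site = cut_site,
         guide_start = guide_start, guide_end = guide_end),
    class = "amplicon_reference"
  )
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat("<amplicon_reference> ", x$name, ": ", nchar(x$sequence), " bp, cut site ",
      x$cut_site, ", protospacer [", x$guide_start, ",", x$guide_end, ")\n",
      sep = "")
  invisible(x)
}

# Fixed 200 bp synthetic amplicon used as the default study locus. The two
# terminal 20-mers are the true TP53 target-region primer pair; the interior
# is a fixed synthetic sequence (this is NOT the genomic TP53 amplicon) with
# an NGG PAM placed immediately 3' of the protospacer. Cut site 100 sits
# 3 bp upstream of the PAM, the canonical SpCas9 blunt-cut position.
.TP53_SYNTH_AMPLICON <- paste0(
  "CCTGGTCCTCTGACTGCTCTATGACAGGCCGGAAACCCCGAGAAAACAACCCATGATGCC",
  "CCGTTTCTAGCATTAGTCCGGCCTTCCACCCCAGGTCGGTCTGGGGATATAGCTGAATCA",
  "TTTAAAGCAAGGGCCCTGTCCTGGTGACCAGGCGCATCTATGGTATCTAGCGGAACCCTT",
  "CAGAAAACCTACCAGGGCAG"
)

#' Default synthetic TP53-style amplicon
#'
#' A fixed 200 bp amplicon emulating the sequenced TP53 target region: the
#' terminal 20 bp on each side are the actual TP53 target-region primers
#' (forward `CCTGGTCCTCTGACTGCTCT`; the 3' end is the reverse complement of
#' the reverse primer `CTGCCCTGGTAGGTTTTCTG`), and the interior is a fixed
#' synthetic sequence carrying a 20 bp protospacer with an NGG PAM. This is a
#' synthetic stand-in for the genomic amplicon, suitable for simulation and
#' testing; analyses of real data should supply the true reference via
#' [amplicon_reference()] or [read_amplicon_reference()].
#'
#' @return An `amplicon_reference` (200 bp; cut site 100; protospacer
#'   `[83,103)`, 0-based half-open).
#' @examples
#' tp53_amplicon()
#' @export
tp53_amplicon <- function() {
  amplicon_reference(.TP53_SYNTH_AMPLICON, cut_site = 100L,
                     guide_start = 83L, guide_end = 103L,
                     name = "TP53_synthetic_amplicon")
}

#' Read and write an amplicon reference (FASTA + annotation TSV)
#'
#' The reference is stored as a standard FASTA file plus a small BED-like
#' annotation TSV with columns `name`, `cut_site`, `guide_start`,
#' `guide_end` (0-based half-open).
#'
#' @param fasta Path to the reference FASTA (first record used).
#' @param annotation Path to the annotation TSV.
#' @return `read_amplicon_reference()` returns an `amplicon_reference`;
#'   `write_amplicon_reference()` returns the input invisibly.
#' @export
read_amplicon_reference <- function(fasta, annotation) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop("no sequences in ", fasta)
  ann <- utils::read.delim(annotation, stringsAsFactors = FALSE)
  needed <- c("name", "cut_site", "guide_start", "guide_end")
  if (!all(needed %in% names(ann))) {
    stop("annotation must have columns: ", paste(needed, collapse = ", "))
  }
  amplicon_reference(as.character(seqs[[1L]]),
                     cut_site = ann$cut_site[1L],
                     guide_start = ann$guide_start[1L],
                     guide_end = ann$guide_end[1L],
                     name = ann$name[1L])
}

#' @rdname read_amplicon_reference
#' @param ref An `amplicon_reference`.
#' @export
write_amplicon_reference <- function(ref, fasta, annotation) {
  stopifnot(inherits(ref, "amplicon_reference"))
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- ref$name
  Biostrings::writeXStringSet(x, fasta)
  ann <- data.frame(name = ref$name, cut_site = ref$cut_site,
                    guide_start = ref$guide_start, guide_end = ref$guide_end)
  utils::write.table(ann, annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ref)
}
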