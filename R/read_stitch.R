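# Merge forward/reverse mates into observed sequences (3'-overlap stitching
# with quality-based consensus) and enforce the terminal wild-type anchor
# filter. An observed sequence is one reconstructed molecule ready for
# breakpoint calling.

#' Reverse complement of a nucleotide string
#'
#' Standard Watson-Crick complement, reversed; `N` maps to `N`.
#'
#' @param seq Nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("ACGT")
#' reverse_complement("CCTGGTCCTCTGACTGCTCT")  # TP53 forward primer
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop("non-nucleotide character '", substr(seq, bad, bad),
         "' at position ", bad)
  }
  if (!nzchar(seq)) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Phred+33 string -> integer vector
.qual_to_int <- function(qual) {
  utf8ToInt(qual) - 33L
}

# mismatch indicator between two equal-length raw vectors; N counts as
# mismatch everywhere
.RAW_N <- charToRaw("N")
.mismatch_raw <- function(a, b) {
  (a != b) | a == .RAW_N | b == .RAW_N
}

#' Stitch a read pair into an observed sequence
#'
#' The reverse mate is reverse-complemented and the two reads are merged at
#' the 3'-overlap junction: among candidate overlaps of length at least
#' `min_overlap` between the forward read's 3' end and the oriented reverse
#' read's 5' end, the overlap with the fewest mismatches wins (ties go to
#' the longest overlap), provided its mismatch fraction does not exceed
#' `max_overlap_mismatch_frac`. At discordant overlap positions the base
#' with the higher Phred score is kept (ties keep the forward base). `N`
#' counts as a mismatch.
#'
#' @param forward_seq,reverse_seq Mate sequences (reverse as sequenced, i.e.
#'   not yet complemented).
#' @param forward_qual,reverse_qual Phred+33 quality strings aligned to the
#'   mates.
#' @param min_overlap Minimum admissible overlap (bp).
#' @param max_overlap_mismatch_frac Maximum mismatch fraction tolerated
#'   within the chosen overlap.
#' @return A list: `sequence` (stitched sequence or `NA`), `overlap_length`,
#'   `stitched` (logical), `reject_reason` (`NA`, `"no_overlap"`, or
#'   `"ambiguous_overlap"`). Stitched length is always
#'   `nchar(forward) + nchar(reverse) - overlap_length`.
#' @examples
#' mol <- paste(rep("ACGT", 10), collapse = "")
#' f <- substr(mol, 1, 25)
#' r <- reverse_complement(substr(mol, 11, 40))
#' q <- strrep("I", 25); q2 <- strrep("I", 30)
#' stitch_pair(f, r, q, q2)$overlap_length
#' @export
stitch_pair <- function(forward_seq, reverse_seq, forward_qual, reverse_qual,
                        min_overlap = 15L, max_overlap_mismatch_frac = 0.1) {
  if (!nzchar(forward_seq) || !nzchar(reverse_seq)) {
    stop("both mates must be non-empty")
  }
  if (nchar(forward_seq) != nchar(forward_qual) ||
      nchar(reverse_seq) != nchar(reverse_qual)) {
    stop("sequence and quality lengths must match per mate")
  }
  r_or <- reverse_complement(reverse_seq)
  rq_or <- rev(.qual_to_int(reverse_qual))
  .stitch_core(charToRaw(forward_seq), charToRaw(r_or),
               .qual_to_int(forward_qual), rq_or,
               as.integer(min_overlap), max_overlap_mismatch_frac)
}

.stitch_core <- function(f_raw, r_raw, f_q, r_q, min_overlap, max_mm_frac) {
  lf <- length(f_raw)
  lr <- length(r_raw)
  o_max <- min(lf, lr)
  reject <- function(reason) {
    list(sequence = NA_character_, overlap_length = NA_integer_,
         stitched = FALSE, reject_reason = reason)
  }
  if (o_max < min_overlap) return(reject("no_overlap"))

  best_o <- NA_integer_
  best_mm <- Inf
  # fewest mismatches wins; ties go to the longest overlap. Scanning o
  # descending means only a strictly smaller mismatch count replaces the
  # incumbent, and a mismatch-free candidate can never be beaten.
  for (o in o_max:min_overlap) {
    mm <- sum(.mismatch_raw(f_raw[(lf - o + 1L):lf], r_raw[1:o]))
    if (mm > o * max_mm_frac) next
    if (mm < best_mm) {
      best_mm <- mm
      best_o <- o
      if (mm == 0L) break
    }
  }
  if (is.na(best_o)) return(reject("no_overlap"))

  o <- best_o
  f_ov <- (lf - o + 1L):lf
  cons <- f_raw[f_ov]
  use_r <- r_q[1:o] > f_q[f_ov]      # higher Phred wins; tie keeps forward
  cons[use_r] <- r_raw[1:o][use_r]
  stitched <- rawToChar(c(f_raw[seq_len(lf - o)], cons,
                          if (o < lr) r_raw[(o + 1L):lr] else raw(0)))
  list(sequence = stitched, overlap_length = o, stitched = TRUE,
       reject_reason = NA_character_)
}

#' Check the terminal wild-type anchors of a stitched sequence
#'
#' An observed sequence is analysed only if both of its ends — each the 5'
#' end of one mate — carry wild-type sequence: the first `anchor_len` bases
#' must match the reference's first `anchor_len` bases and the last
#' `anchor_len` bases its last `anchor_len` bases, each with at most
#' `max_anchor_mismatches` mismatches (`N` counts as mismatch).
#'
#' @param sequence Stitched observed sequence.
#' @param ref An [amplicon_reference()] (or a plain reference string).
#' @param anchor_len Anchor length in bp.
#' @param max_anchor_mismatches Mismatches tolerated per anchor.
#' @return `TRUE`/`FALSE`, with attribute `reason = "too_short"` when the
#'   sequence is shorter than `2 * anchor_len`.
#' @examples
#' ref <- tp53_amplicon()
#' check_wildtype_anchor(ref$sequence, ref)
#' @export
check_wildtype_anchor <- function(sequence, ref, anchor_len = 40L,
                                  max_anchor_mismatches = 0L) {
  ref_seq <- if (inherits(ref, "amplicon_reference")) ref$sequence else ref
  anchor_len <- as.integer(anchor_len)
  n <- nchar(sequence)
  if (n < 2L * anchor_len) {
    return(structure(FALSE, reason = "too_short"))
  }
  s_raw <- charToRaw(sequence)
  r_raw <- charToRaw(ref_seq)
  nr <- length(r_raw)
  head_mm <- sum(.mismatch_raw(s_raw[1:anchor_len], r_raw[1:anchor_len]))
  tail_mm <- sum(.mismatch_raw(s_raw[(n - anchor_len + 1L):n],
                               r_raw[(nr - anchor_len + 1L):nr]))
  head_mm <= max_anchor_mismatches && tail_mm <= max_anchor_mismatches
}

#' Stitch all pairs of a sample and apply the anchor filter
#'
#' Driver over a read-pair data frame. Pairs that fail to stitch are kept in
#' the output with a machine-readable rejection reason so the run can be
#' fully accounted for.
#'
#' @param pairs Read-pair data frame (`read_id`, `forward_seq`,
#'   `reverse_seq`, `forward_qual`, `reverse_qual`).
#' @param ref An [amplicon_reference()]; when supplied, `anchor_ok` is
#'   computed for every stitched sequence.
#' @inheritParams stitch_pair
#' @inheritParams check_wildtype_anchor
#' @return Data frame: `read_id`, `sequence`, `overlap_length`, `stitched`,
#'   `reject_reason`, `anchor_ok`.
#' @export
stitch_pairs <- function(pairs, ref = NULL, min_overlap = 15L,
                         max_overlap_mismatch_frac = 0.1,
                         anchor_len = 40L, max_anchor_mismatches = 0L) {
  n <- nrow(pairs)
  seqs <- character(n)
  ovl <- integer(n)
  ok <- logical(n)
  reason <- character(n)
  r_or_all <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(pairs$reverse_seq)))
  for (i in seq_len(n)) {
    res <- .stitch_core(charToRaw(pairs$forward_seq[i]),
                        charToRaw(r_or_all[i]),
                        .qual_to_int(pairs$forward_qual[i]),
                        rev(.qual_to_int(pairs$reverse_qual[i])),
                        as.integer(min_overlap), max_overlap_mismatch_frac)
    seqs[i] <- res$sequence
    ovl[i] <- res$overlap_length
    ok[i] <- res$stitched
    reason[i] <- res$reject_reason
  }
  anchor_ok <- rep(NA, n)
  if (!is.null(ref)) {
    for (i in which(ok)) {
      anchor_ok[i] <- as.logical(check_wildtype_anchor(
        seqs[i], ref, anchor_len, max_anchor_mismatches))
    }
  }
  data.frame(read_id = pairs$read_id, sequence = seqs, overlap_length = ovl,
             stitched = ok, reject_reason = reason, anchor_ok = anchor_ok,
             stringsAsFactors = FALSE)
}

#' Write stitched sequences and the rejection log
#'
#' Stitched sequences go to FASTA; rejected pairs to a TSV log of
#' `read_id`, `reason`.
#'
#' @param stitched Output of [stitch_pairs()].
#' @param fasta_path,log_path Output paths.
#' @export
write_stitched <- function(stitched, fasta_path, log_path) {
  keep <- stitched[stitched$stitched, , drop = FALSE]
  x <- Biostrings::DNAStringSet(keep$sequence)
  names(x) <- keep$read_id
  Biostrings::writeXStringSet(x, fasta_path)
  rej <- stitched[!stitched$stitched, c("read_id", "reject_reason")]
  names(rej) <- c("read_id", "reason")
  utils::write.table(rej, log_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, log_path))
}
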