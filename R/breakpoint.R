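# Two-sided breakpoint calling: the observed sequence is compared with the
# wild-type amplicon starting from both ends and moving inward, without
# gaps. A breakpoint is placed where the two first differ by at least two
# consecutive mismatches; isolated single mismatches (sequencing errors)
# never trigger one. The wild-type sequence between the breakpoints is the
# deletion region; the observed sequence between them is the insertion
# region. All reference coordinates are 0-based, half-open.

# first position (0-based) of the first run of >= 2 consecutive mismatches
# between two raw vectors compared at equal offsets; NA if none within
# min(length) - 1
.first_double_mismatch <- function(obs_raw, ref_raw) {
  m <- min(length(obs_raw), length(ref_raw))
  if (m < 2L) return(NA_integer_)
  mm <- .mismatch_raw(obs_raw[1:m], ref_raw[1:m])
  hit <- which(mm[-m] & mm[-1L])
  if (!length(hit)) NA_integer_ else hit[1L] - 1L
}

#' Forward breakpoint of an observed sequence
#'
#' With the observed and wild-type sequences left-aligned (position `i`
#' against position `i`), returns the smallest 0-based offset `i` such that
#' both `i` and `i + 1` mismatch — the position where the sequences first
#' begin to differ by at least two consecutive mismatches. Returns `NA` if
#' no such position exists within the shorter sequence. `N` counts as a
#' mismatch.
#'
#' @param obs Observed (stitched) sequence.
#' @param ref Wild-type sequence (string or [amplicon_reference()]).
#' @return 0-based offset, or `NA_integer_`.
#' @examples
#' forward_breakpoint("AAAACCAA", "AAAAAAAA")  # 4
#' forward_breakpoint("AACAAAAA", "AAAAAAAA")  # NA: isolated mismatch
#' @export
forward_breakpoint <- function(obs, ref) {
  ref <- if (inherits(ref, "amplicon_reference")) ref$sequence else ref
  if (!nzchar(obs) || !nzchar(ref)) stop("empty sequence")
  .first_double_mismatch(charToRaw(obs), charToRaw(ref))
}

#' Reverse breakpoint of an observed sequence
#'
#' Mirror of [forward_breakpoint()] with the sequences right-aligned (last
#' base against last base) and scanned inward from the right. The returned
#' offset is in reference coordinates and half-open exclusive: it is the
#' reference position just after the last disrupted reference base, i.e. the
#' end of the deletion interval. Equivalently
#' `nchar(ref) - forward_breakpoint(reverse(obs), reverse(ref))`.
#'
#' @inheritParams forward_breakpoint
#' @return 0-based reference offset, or `NA_integer_`.
#' @examples
#' reverse_breakpoint("AAAACCAA", "AAAAAAAA")  # 6
#' @export
reverse_breakpoint <- function(obs, ref) {
  ref <- if (inherits(ref, "amplicon_reference")) ref$sequence else ref
  if (!nzchar(obs) || !nzchar(ref)) stop("empty sequence")
  j <- .first_double_mismatch(rev(charToRaw(obs)), rev(charToRaw(ref)))
  if (is.na(j)) NA_integer_ else nchar(ref) - j
}

.CALL_COLS <- c("read_id", "forward_breakpoint", "reverse_breakpoint",
                "deletion_start", "deletion_end", "inserted_sequence",
                "status", "length_difference", "note")

.call_row <- function(read_id, f = NA_integer_, r = NA_integer_,
                      ds = NA_integer_, de = NA_integer_, ins = "",
                      status, ldiff = 0L, note = NA_character_) {
  data.frame(read_id = read_id, forward_breakpoint = f, reverse_breakpoint = r,
             deletion_start = ds, deletion_end = de, inserted_sequence = ins,
             status = status, length_difference = ldiff, note = note,
             stringsAsFactors = FALSE)
}

#' Call the indel of one observed sequence
#'
#' Scans for the forward and reverse breakpoints and derives the deletion
#' region (wild-type sequence between the breakpoints) and insertion region
#' (observed sequence between the breakpoints).
#'
#' Because the scans tolerate isolated mismatches and stop only at double
#' mismatches, chance matches in the disrupted region can push the two
#' breakpoints past each other, which would imply a negative-length region.
#' Such crossings are reconciled deterministically: the overhang is split
#' evenly between the two breakpoints, the region on the net-indel side
#' keeps length `|nchar(obs) - nchar(ref)|`, and the other region becomes
#' empty. The reconciled call remains consistent with both scans (no double
#' mismatch outside the called region in either frame) and is marked in the
#' `note` column as `boundary_reconciled`.
#'
#' Calls whose deletion and insertion regions are both longer than
#' `artifact_min_len` are flagged `status = "artifact"`: paired long
#' insertion/deletion regions are the signature of the breakpoint caller
#' stopping early on a stretch of poor sequence (typically low-quality
#' reverse-read tails) and are excluded from positional statistics
#' downstream.
#'
#' @param obs Observed (stitched) sequence.
#' @param ref An [amplicon_reference()] or reference string.
#' @param read_id Identifier carried into the call record.
#' @param anchor_ok Whether the sequence passed the wild-type anchor check;
#'   `FALSE` yields `status = "unanchored"` with no breakpoint calling.
#' @param artifact_min_len Minimum deletion and insertion length (bp) for a
#'   call to be flagged as a long-region artifact.
#' @return One-row data frame: `read_id`, `forward_breakpoint`,
#'   `reverse_breakpoint` (reference coordinates, reconciled),
#'   `deletion_start`, `deletion_end`, `inserted_sequence`, `status` (one of
#'   `wildtype_like`, `edited`, `artifact`, `unanchored`),
#'   `length_difference` (`nchar(obs) - nchar(ref)`), `note`
#'   (`NA`, `one_sided_breakpoint`, or `boundary_reconciled`).
#' @examples
#' ref <- tp53_amplicon()
#' obs <- paste0(substr(ref$sequence, 1, 97), substr(ref$sequence, 104, 200))
#' call_indel(obs, ref)[, c("deletion_start", "deletion_end", "status")]
#' @export
call_indel <- function(obs, ref, read_id = "obs", anchor_ok = TRUE,
                       artifact_min_len = 25L) {
  ref_seq <- if (inherits(ref, "amplicon_reference")) ref$sequence else ref
  if (!isTRUE(as.logical(anchor_ok))) {
    return(.call_row(read_id, status = "unanchored",
                     ldiff = nchar(obs) - nchar(ref_seq)))
  }
  len_obs <- nchar(obs)
  len_ref <- nchar(ref_seq)
  ldiff <- len_obs - len_ref

  obs_raw <- charToRaw(obs)
  ref_raw <- charToRaw(ref_seq)
  f <- .first_double_mismatch(obs_raw, ref_raw)
  j <- .first_double_mismatch(rev(obs_raw), rev(ref_raw))

  if (is.na(f) && is.na(j)) {
    return(.call_row(read_id, status = "wildtype_like", ldiff = ldiff))
  }
  if (is.na(f) || is.na(j)) {
    # a lone disrupted end cannot define regions; treated as wild-type-like
    # and annotated so the run report can count these
    return(.call_row(read_id,
                     f = if (is.na(f)) NA_integer_ else f,
                     r = if (is.na(j)) NA_integer_ else len_ref - j,
                     status = "wildtype_like", ldiff = ldiff,
                     note = "one_sided_breakpoint"))
  }

  r_ref <- len_ref - j
  r_obs <- len_obs - j
  note <- NA_character_

  if (f > min(r_ref, r_obs)) {
    # crossing: split the overhang evenly, net region keeps |ldiff|
    over <- f - min(r_ref, r_obs)
    f <- f - over %/% 2L
    if (ldiff <= 0L) {          # net deletion (or length-neutral)
      r_obs <- f
      r_ref <- f - ldiff
    } else {                    # net insertion
      r_ref <- f
      r_obs <- f + ldiff
    }
    note <- "boundary_reconciled"
  }

  del_len <- r_ref - f
  ins_seq <- if (r_obs > f) substr(obs, f + 1L, r_obs) else ""
  ins_len <- nchar(ins_seq)

  if (del_len == 0L && ins_len == 0L) {
    return(.call_row(read_id, f = f, r = r_ref, status = "wildtype_like",
                     ldiff = ldiff, note = note))
  }
  status <- if (del_len >= artifact_min_len && ins_len >= artifact_min_len) {
    "artifact"
  } else {
    "edited"
  }
  .call_row(read_id, f = f, r = r_ref,
            ds = if (del_len > 0L) f else NA_integer_,
            de = if (del_len > 0L) r_ref else NA_integer_,
            ins = ins_seq, status = status, ldiff = ldiff, note = note)
}

#' Call indels for all stitched sequences of a sample
#'
#' Driver over the output of [stitch_pairs()]. Pairs that failed stitching
#' are skipped; stitched sequences that failed the anchor check are reported
#' as `unanchored`.
#'
#' @param stitched Data frame from [stitch_pairs()].
#' @param ref An [amplicon_reference()].
#' @inheritParams call_indel
#' @return Data frame of calls, one row per stitched sequence.
#' @export
call_indels <- function(stitched, ref, artifact_min_len = 25L) {
  keep <- stitched[stitched$stitched, , drop = FALSE]
  out <- vector("list", nrow(keep))
  for (i in seq_len(nrow(keep))) {
    out[[i]] <- call_indel(keep$sequence[i], ref,
                           read_id = keep$read_id[i],
                           anchor_ok = isTRUE(keep$anchor_ok[i]),
                           artifact_min_len = artifact_min_len)
  }
  do.call(rbind, out)
}

#' Signed length difference of a call
#'
#' Number of bases by which the observed sequence differs in length from
#' wild type: `nchar(obs) - nchar(ref)`, which for every non-artifact call
#' equals `nchar(insertion) - nchar(deletion)`. This is the quantity the
#' length-based indel efficiency counts; a call with an insertion and a
#' deletion of the same length is length-neutral (difference 0).
#'
#' @param call One-row call data frame from [call_indel()].
#' @return Signed integer (bp).
#' @export
length_difference <- function(call) {
  call$length_difference
}

#' Write per-read calls to TSV
#'
#' @param calls Data frame from [call_indels()].
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
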