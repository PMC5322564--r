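# Sample-level aggregation of per-read indel calls: length-based indel
# efficiency, per-position edited fractions, deletion/insertion length
# distributions, ranked pattern tables and the deletion pileup.

# anchor-passing calls (everything except unanchored)
.anchored <- function(calls) {
  calls[calls$status != "unanchored", , drop = FALSE]
}

# calls usable for positional statistics and length histograms: anchored,
# long-region artifacts excluded
.positional <- function(calls) {
  calls[!(calls$status %in% c("unanchored", "artifact")), , drop = FALSE]
}

.del_len <- function(calls) {
  d <- calls$deletion_end - calls$deletion_start
  d[is.na(d)] <- 0L
  d
}

#' Length-based indel efficiency of a sample
#'
#' Percentage of anchor-passing observed sequences whose length differs
#' from the wild-type sequence. Edited sequences with an insertion and a
#' deletion of the same length are length-neutral and are not counted.
#'
#' @param calls Call data frame from [call_indels()].
#' @return Percentage in `[0, 100]`.
#' @examples
#' calls <- data.frame(status = c("edited", "wildtype_like"),
#'                     deletion_start = c(10L, NA), deletion_end = c(16L, NA),
#'                     inserted_sequence = c("", ""),
#'                     length_difference = c(-6L, 0L))
#' indel_efficiency(calls)  # 50
#' @export
indel_efficiency <- function(calls) {
  calls <- .anchored(calls)
  if (nrow(calls) == 0L) stop("no anchor-passing sequences; efficiency undefined")
  100 * mean(calls$length_difference != 0L)
}

#' Fraction of sequences edited at each reference position
#'
#' For each reference position `p`, the fraction of anchor-passing,
#' non-artifact sequences in which `p` was edited: either a deletion spans
#' `p`, or the sequence carries an insertion and `p` is one of the two
#' reference bases flanking the insertion junction (`f - 1` and `f`;
#' set `adjacency = "right"` for one-sided marking of `f` only).
#'
#' @param calls Call data frame from [call_indels()].
#' @param ref An [amplicon_reference()].
#' @param adjacency Which reference bases an insertion marks: `"both"`
#'   (default, the two junction-flanking bases) or `"right"`.
#' @return Data frame `position` (0-based), `fraction` in `[0,1]`, one row
#'   per reference position.
#' @export
per_position_edit_fraction <- function(calls, ref, adjacency = c("both", "right")) {
  adjacency <- match.arg(adjacency)
  len <- nchar(ref$sequence)
  calls <- .positional(calls)
  if (nrow(calls) == 0L) stop("no usable calls")
  counts <- integer(len)
  edited <- calls[calls$status == "edited", , drop = FALSE]
  for (i in seq_len(nrow(edited))) {
    pos <- integer(0)
    if (!is.na(edited$deletion_start[i])) {
      pos <- seq.int(edited$deletion_start[i], edited$deletion_end[i] - 1L)
    }
    if (nzchar(edited$inserted_sequence[i])) {
      f <- edited$forward_breakpoint[i]
      adj <- if (adjacency == "both") c(f - 1L, f) else f
      pos <- union(pos, adj[adj >= 0L & adj < len])
    }
    counts[pos + 1L] <- counts[pos + 1L] + 1L
  }
  data.frame(position = seq_len(len) - 1L, fraction = counts / nrow(calls))
}

#' Deletion and insertion length distributions
#'
#' Fraction of anchor-passing, non-artifact sequences having a deletion
#' (resp. insertion) of each length. A sequence with both an insertion and
#' a deletion contributes to both distributions. The row at length 0 is the
#' fraction of sequences with no deletion (resp. no insertion).
#'
#' @param calls Call data frame from [call_indels()].
#' @return Data frame `length`, `fraction`; fractions sum to 1.
#' @examples
#' calls <- data.frame(status = "edited", deletion_start = 10L,
#'                     deletion_end = 13L, inserted_sequence = "TAG",
#'                     forward_breakpoint = 10L, length_difference = 0L)
#' deletion_length_hist(calls)
#' @export
deletion_length_hist <- function(calls) {
  calls <- .positional(calls)
  if (nrow(calls) == 0L) stop("no usable calls")
  .length_hist(.del_len(calls))
}

#' @rdname deletion_length_hist
#' @export
insertion_length_hist <- function(calls) {
  calls <- .positional(calls)
  if (nrow(calls) == 0L) stop("no usable calls")
  .length_hist(nchar(calls$inserted_sequence))
}

.length_hist <- function(lens) {
  tab <- table(lens)
  data.frame(length = as.integer(names(tab)),
             fraction = as.numeric(tab) / length(lens))
}

#' Per-position deletion pileup
#'
#' For each reference position, the number of anchor-passing, non-artifact
#' sequences whose deletion interval spans it — the unnormalised,
#' deletions-only companion of [per_position_edit_fraction()].
#'
#' @inheritParams per_position_edit_fraction
#' @return Data frame `position` (0-based), `count`.
#' @export
deletion_pileup <- function(calls, ref) {
  len <- nchar(ref$sequence)
  calls <- .positional(calls)
  counts <- integer(len)
  dels <- calls[!is.na(calls$deletion_start), , drop = FALSE]
  for (i in seq_len(nrow(dels))) {
    idx <- seq.int(dels$deletion_start[i] + 1L, dels$deletion_end[i])
    counts[idx] <- counts[idx] + 1L
  }
  data.frame(position = seq_len(len) - 1L, count = counts)
}

#' Ranked table of the most frequent editing patterns
#'
#' Patterns are keyed by (deletion interval, inserted sequence) and ranked
#' by total count across samples, ties broken by smaller deletion start,
#' then lexicographic insertion. Long-region artifact calls are retained
#' here (their insertion is typically rendered in brackets). Insertions
#' longer than `long_insertion_threshold` are rendered as `[L]` rather than
#' the literal sequence. Each row carries per-sample counts and a rendered
#' alignment line: reference upstream of the forward breakpoint, dashes
#' across the deletion, the insertion (or its bracketed length) at the
#' junction, and reference downstream of the reverse breakpoint.
#'
#' @param calls Call data frame; an optional `sample_id` column yields
#'   per-sample count columns (`count.<sample>`).
#' @param ref An [amplicon_reference()].
#' @param n_top Number of patterns to return.
#' @param long_insertion_threshold Insertions longer than this many bp are
#'   shown as a bracketed length.
#' @param flank Reference context (bp) rendered on each side.
#' @return Data frame: `deletion_start`, `deletion_end`,
#'   `insertion_rendered`, `total`, one `count.<sample>` column per sample,
#'   and `alignment`.
#' @export
top_patterns <- function(calls, ref, n_top = 20L, long_insertion_threshold = 25L,
                         flank = 20L) {
  if (n_top < 1L) stop("n_top must be >= 1")
  calls <- .anchored(calls)
  if (nrow(calls) == 0L) stop("no usable calls")
  if (is.null(calls$sample_id)) calls$sample_id <- "sample1"

  ds <- ifelse(is.na(calls$deletion_start), -1L, calls$deletion_start)
  de <- ifelse(is.na(calls$deletion_end), -1L, calls$deletion_end)
  key <- paste(ds, de, calls$inserted_sequence, sep = "|")

  samples <- sort(unique(calls$sample_id))
  tot <- table(key)
  per <- table(key, calls$sample_id)

  first <- !duplicated(key)
  info <- data.frame(key = key[first], deletion_start = ds[first],
                     deletion_end = de[first],
                     inserted_sequence = calls$inserted_sequence[first],
                     stringsAsFactors = FALSE)
  info$total <- as.integer(tot[info$key])
  # rank: total desc, deletion start asc, insertion lexicographic
  ord <- order(-info$total, info$deletion_start, info$inserted_sequence)
  info <- info[ord, , drop = FALSE][seq_len(min(n_top, nrow(info))), , drop = FALSE]

  ins_rendered <- ifelse(
    nchar(info$inserted_sequence) > long_insertion_threshold,
    paste0("[", nchar(info$inserted_sequence), "]"),
    info$inserted_sequence
  )
  out <- data.frame(deletion_start = ifelse(info$deletion_start < 0L, NA_integer_,
                                            info$deletion_start),
                    deletion_end = ifelse(info$deletion_end < 0L, NA_integer_,
                                          info$deletion_end),
                    insertion_rendered = ins_rendered,
                    total = info$total, stringsAsFactors = FALSE)
  for (s in samples) {
    out[[paste0("count.", s)]] <- as.integer(per[info$key, s])
  }
  out$alignment <- vapply(seq_len(nrow(info)), function(i) {
    .render_pattern(ref, info$deletion_start[i], info$deletion_end[i],
                    ins_rendered[i], flank)
  }, character(1))
  rownames(out) <- NULL
  out
}

.render_pattern <- function(ref, ds, de, ins_rendered, flank) {
  seq <- ref$sequence
  len <- nchar(seq)
  if (ds < 0L) {  # no deletion: insertion (if any) shown at the cut site
    j <- ref$cut_site
    up <- substr(seq, max(1L, j - flank + 1L), j)
    down <- substr(seq, j + 1L, min(len, j + flank))
    mid <- if (nzchar(ins_rendered)) paste0("{", ins_rendered, "}") else ""
    return(paste0(up, mid, down))
  }
  up <- substr(seq, max(1L, ds - flank + 1L), ds)
  down <- substr(seq, de + 1L, min(len, de + flank))
  mid <- paste0(if (nzchar(ins_rendered)) paste0("{", ins_rendered, "}") else "",
                strrep("-", de - ds))
  paste0(up, mid, down)
}

#' Aggregate calls into a sample editing profile
#'
#' Bundles all sample-level summaries: number of anchor-passing sequences,
#' indel efficiency, per-position edited fractions, deletion/insertion
#' length distributions, deletion pileup, status counts and the top pattern
#' table.
#'
#' @param calls Call data frame from [call_indels()].
#' @param ref An [amplicon_reference()].
#' @param sample_id Sample identifier.
#' @inheritParams top_patterns
#' @return An object of class `editing_profile`.
#' @export
editing_profile <- function(calls, ref, sample_id = "sample1", n_top = 20L,
                            long_insertion_threshold = 25L) {
  anchored <- .anchored(calls)
  structure(list(
    sample_id = sample_id,
    n_sequences = nrow(anchored),
    status_counts = table(calls$status),
    indel_efficiency = indel_efficiency(calls),
    per_position = per_position_edit_fraction(calls, ref),
    deletion_length_hist = deletion_length_hist(calls),
    insertion_length_hist = insertion_length_hist(calls),
    deletion_pileup = deletion_pileup(calls, ref),
    pattern_table = top_patterns(calls, ref, n_top = n_top,
                                 long_insertion_threshold = long_insertion_threshold),
    reference = ref
  ), class = "editing_profile")
}

#' @export
print.editing_profile <- function(x, ...) {
  cat("<editing_profile> sample ", x$sample_id, "\n",
      "  anchor-passing sequences: ", x$n_sequences, "\n",
      "  indel efficiency: ", sprintf("%.2f%%", x$indel_efficiency), "\n",
      "  peak edited fraction: ",
      sprintf("%.3f at position %d",
              max(x$per_position$fraction),
              x$per_position$position[which.max(x$per_position$fraction)]),
      "\n", sep = "")
  invisible(x)
}

#' Write profile tables to TSV
#'
#' Writes `<prefix>_per_position.tsv`, `<prefix>_deletion_lengths.tsv`,
#' `<prefix>_insertion_lengths.tsv`, `<prefix>_pileup.tsv` and
#' `<prefix>_patterns.tsv`.
#'
#' @param profile An [editing_profile()].
#' @param prefix Output path prefix.
#' @export
write_profile <- function(profile, prefix) {
  w <- function(df, suffix) {
    utils::write.table(df, paste0(prefix, suffix), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(profile$per_position, "_per_position.tsv")
  w(profile$deletion_length_hist, "_deletion_lengths.tsv")
  w(profile$insertion_length_hist, "_insertion_lengths.tsv")
  w(profile$deletion_pileup, "_pileup.tsv")
  w(profile$pattern_table, "_patterns.tsv")
  invisible(prefix)
}

#' Three-panel editing summary plot
#'
#' Per-position edited fraction, deletion length distribution and insertion
#' length distribution for one sample (requires ggplot2).
#'
#' @param profile An [editing_profile()].
#' @return A patchwork-free list of three ggplot objects (per_position,
#'   deletions, insertions).
#' @export
plot_editing_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  p1 <- gg(profile$per_position, aes(x = position, y = fraction)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_vline(xintercept = profile$reference$cut_site,
                        linetype = "dashed") +
    ggplot2::labs(x = "reference position (0-based)",
                  y = "fraction edited", title = profile$sample_id)
  d <- profile$deletion_length_hist
  p2 <- gg(d[d$length > 0, ], aes(x = length, y = fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "deletion length (bp)", y = "fraction of sequences")
  i <- profile$insertion_length_hist
  p3 <- gg(i[i$length > 0, ], aes(x = length, y = fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "insertion length (bp)", y = "fraction of sequences")
  list(per_position = p1, deletions = p2, insertions = p3)
}
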