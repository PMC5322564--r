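# Ground-truthed amplicon read simulator. Generates edited molecules around
# the cut site, then MiSeq-style 2x150 bp paired reads with substitution
# errors and Phred qualities, so the stitcher and breakpoint caller can be
# validated against known truth.

.ANCHOR_DEFAULT <- 40L

#' Simulation configuration
#'
#' Parameters of the synthetic amplicon sequencing experiment. Defaults
#' describe the study conditions emulated throughout the package: a 200 bp
#' amplicon sequenced with 2x150 bp paired-end reads at 10,000 pairs per
#' sample, 60% of molecules edited, geometric deletion lengths clustered at
#' the cut site, occasional junction insertions, and a low uniform
#' substitution error rate with a quality ramp on the reverse-read 3' end.
#'
#' Length distributions are given as `list(name, ...)` with `name` one of:
#' `"fixed"` (parameter `length`), `"uniform"` (`min`, `max`, integers), or
#' `"geometric"` (`prob`; lengths are `1 + rgeom(prob)`, support >= 1).
#'
#' @param reference An [amplicon_reference()]; defaults to [tp53_amplicon()].
#' @param edited_fraction Probability a molecule is edited, in `[0,1]`.
#' @param deletion_length_distribution Deletion length distribution (see
#'   Details). Lengths of 0 are permitted (e.g. `uniform` with `min = 0`):
#'   such molecules carry only an insertion, placed at the cut site.
#' @param insertion_probability Probability an edited molecule also carries
#'   an insertion at the deletion junction, in `[0,1]`.
#' @param insertion_length_distribution Insertion length distribution.
#' @param substitution_error_rate Per-base substitution error probability on
#'   reads, in `[0,1]`.
#' @param nonadjacent_errors If `TRUE`, substitution errors within a read are
#'   thinned so that no two fall on adjacent bases (a validation device for
#'   exercising the two-consecutive-mismatch rule; the realised error rate is
#'   then marginally below nominal).
#' @param read_length Read length in bp (both mates).
#' @param n_molecules Number of molecules (read pairs) per sample.
#' @param anchor_len Length of the terminal wild-type anchors (bp) that
#'   deletions must not invade.
#' @param qual_high,qual_low,reverse_ramp_len Phred quality model: both reads
#'   carry `qual_high` everywhere except the last `reverse_ramp_len` bases of
#'   the reverse read, which decline linearly to `qual_low` (emulating the
#'   low-quality reverse-read 3' ends seen on real instruments).
#' @param rng_seed Integer seed; all simulator output is deterministic given
#'   the configuration including this seed.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- simulation_config(n_molecules = 100, rng_seed = 7)
#' cfg$edited_fraction
#' @export
simulation_config <- function(reference = tp53_amplicon(),
                              edited_fraction = 0.6,
                              deletion_length_distribution = list(name = "geometric", prob = 0.3),
                              insertion_probability = 0.2,
                              insertion_length_distribution = list(name = "geometric", prob = 0.5),
                              substitution_error_rate = 0.001,
                              nonadjacent_errors = FALSE,
                              read_length = 150L,
                              n_molecules = 10000L,
                              anchor_len = .ANCHOR_DEFAULT,
                              qual_high = 37L,
                              qual_low = 20L,
                              reverse_ramp_len = 50L,
                              rng_seed = 1L) {
  stopifnot(inherits(reference, "amplicon_reference"))
  for (p in c(edited_fraction, insertion_probability, substitution_error_rate)) {
    if (!is.numeric(p) || p < 0 || p > 1) stop("probabilities must lie in [0,1]")
  }
  read_length <- as.integer(read_length)
  n_molecules <- as.integer(n_molecules)
  anchor_len <- as.integer(anchor_len)
  amp_len <- nchar(reference$sequence)
  if (2L * read_length - amp_len < 15L) {
    stop("2*read_length - amplicon_length must be >= 15 so mates can overlap")
  }
  if (reference$cut_site < anchor_len || reference$cut_site > amp_len - anchor_len) {
    stop("cut_site must lie within [anchor_len, amplicon_length - anchor_len]")
  }
  .check_length_dist(deletion_length_distribution, allow_zero = TRUE)
  .check_length_dist(insertion_length_distribution, allow_zero = FALSE)
  structure(
    list(reference = reference,
         edited_fraction = edited_fraction,
         deletion_length_distribution = deletion_length_distribution,
         insertion_probability = insertion_probability,
         insertion_length_distribution = insertion_length_distribution,
         substitution_error_rate = substitution_error_rate,
         nonadjacent_errors = isTRUE(nonadjacent_errors),
         read_length = read_length,
         n_molecules = n_molecules,
         anchor_len = anchor_len,
         qual_high = as.integer(qual_high),
         qual_low = as.integer(qual_low),
         reverse_ramp_len = as.integer(reverse_ramp_len),
         rng_seed = as.integer(rng_seed)),
    class = "sim_config"
  )
}

.check_length_dist <- function(d, allow_zero) {
  if (!is.list(d) || is.null(d$name)) stop("length distribution must be list(name, ...)")
  switch(d$name,
    fixed = {
      if (is.null(d$length) || d$length < if (allow_zero) 0 else 1)
        stop("fixed distribution needs a non-negative 'length'")
    },
    uniform = {
      lo <- if (allow_zero) 0 else 1
      if (is.null(d$min) || is.null(d$max) || d$min < lo || d$max < d$min)
        stop("uniform distribution needs valid 'min' <= 'max'")
    },
    geometric = {
      if (is.null(d$prob) || d$prob <= 0 || d$prob > 1)
        stop("geometric distribution needs 'prob' in (0,1]")
    },
    stop("unknown length distribution: ", d$name)
  )
  invisible(TRUE)
}

.draw_length <- function(d, n = 1L) {
  switch(d$name,
    fixed = rep.int(as.integer(d$length), n),
    uniform = sample(seq.int(d$min, d$max), n, replace = TRUE),
    geometric = 1L + stats::rgeom(n, d$prob)
  )
}

.rand_bases <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate edited and unedited amplicon molecules with ground truth
#'
#' Draws `n_molecules` molecules from the configured editing model. Each
#' molecule is edited with probability `edited_fraction`; an edited molecule
#' carries a deletion whose interval contains (or abuts) the cut site, placed
#' uniformly over admissible placements, and, independently with
#' `insertion_probability`, a random insertion at the deletion junction.
#' Deletions never invade the terminal wild-type anchors: a drawn deletion
#' that cannot be placed is redrawn (up to `max_retries`, then an error).
#'
#' @param config A [simulation_config()].
#' @param max_retries Redraw cap for inadmissible deletion draws.
#' @return A list with `sequences` (character vector of molecule sequences)
#'   and `truth` (data frame: `molecule_id`, `deletion_start`,
#'   `deletion_end` (0-based half-open; `NA` when no deletion),
#'   `inserted_sequence`, `is_edited`).
#' @examples
#' sim <- simulate_molecules(simulation_config(n_molecules = 5, rng_seed = 1))
#' sim$truth
#' @export
simulate_molecules <- function(config, max_retries = 100L) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$rng_seed, .simulate_molecules_impl(config, max_retries))
}

.simulate_molecules_impl <- function(config, max_retries) {
  ref <- config$reference
  wt <- ref$sequence
  len <- nchar(wt)
  cut <- ref$cut_site
  a <- config$anchor_len
  n <- config$n_molecules
  edited <- stats::runif(n) < config$edited_fraction

  seqs <- character(n)
  del_start <- rep(NA_integer_, n)
  del_end <- rep(NA_integer_, n)
  ins <- character(n)

  for (i in seq_len(n)) {
    if (!edited[i]) {
      seqs[i] <- wt
      next
    }
    # deletion draw: length from the configured distribution, start uniform
    # over placements whose closed interval [s, s+L] contains the cut site
    # and whose half-open interval stays clear of both anchors
    L <- NA_integer_
    s <- NA_integer_
    for (try in seq_len(max_retries)) {
      L_try <- .draw_length(config$deletion_length_distribution)
      if (L_try == 0L) { L <- 0L; s <- cut; break }
      lo <- max(cut - L_try, a)
      hi <- min(cut, len - a - L_try)
      if (lo > hi) next  # would invade an anchor; redraw
      L <- L_try
      s <- if (lo == hi) lo else sample(seq.int(lo, hi), 1L)
      break
    }
    if (is.na(L)) {
      stop("could not place a deletion of any drawn length after ",
           max_retries, " retries; check the deletion length distribution")
    }
    ins_seq <- ""
    if (stats::runif(1) < config$insertion_probability) {
      ins_seq <- .rand_bases(.draw_length(config$insertion_length_distribution))
    }
    if (L == 0L && !nzchar(ins_seq)) {
      # degenerate draw: empty deletion and no insertion leaves wild type
      seqs[i] <- wt
      edited[i] <- FALSE
      next
    }
    seqs[i] <- paste0(substr(wt, 1L, s), ins_seq, substr(wt, s + L + 1L, len))
    if (L > 0L) { del_start[i] <- s; del_end[i] <- s + L }
    ins[i] <- ins_seq
  }

  truth <- data.frame(
    molecule_id = sprintf("mol%06d", seq_len(n)),
    deletion_start = del_start,
    deletion_end = del_end,
    inserted_sequence = ins,
    is_edited = edited,
    stringsAsFactors = FALSE
  )
  list(sequences = seqs, truth = truth)
}

.phred_string <- function(quals) {
  intToUtf8(quals + 33L)
}

# Biostrings FASTQ I/O routes qualities through metadata columns and warns
# when they are (as intended) dropped from the sequence container; the
# qualities themselves are carried separately, so the warning is noise here
.quiet_mcols <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("metadata columns", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' Apply random substitution errors to sequences
#'
#' Per-base substitutions at the given rate, each to a uniformly chosen
#' different base. With `nonadjacent = TRUE`, errors are thinned so no two
#' fall on adjacent positions of the same sequence — a validation device
#' for exercising the caller's tolerance of isolated mismatches (the
#' realised rate is then marginally below nominal). Uses the current RNG
#' state; seed externally for reproducibility.
#'
#' @param seqs Character vector of nucleotide sequences.
#' @param rate Per-base substitution probability.
#' @param nonadjacent Forbid adjacent errors within a sequence.
#' @return Character vector with errors applied.
#' @export
add_substitution_errors <- function(seqs, rate, nonadjacent = FALSE) {
  vapply(seqs, .apply_substitutions, character(1), rate = rate,
         nonadjacent = nonadjacent, USE.NAMES = FALSE)
}

.apply_substitutions <- function(seq, rate, nonadjacent) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate)
  if (nonadjacent && length(hit) > 1L) {
    # greedy thinning: drop any error directly following a kept one
    keep <- logical(length(hit))
    last <- -2L
    for (k in seq_along(hit)) {
      if (hit[k] > last + 1L) { keep[k] <- TRUE; last <- hit[k] }
    }
    hit <- hit[keep]
  }
  if (!length(hit)) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in hit) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Turn molecules into error-bearing paired-end reads
#'
#' The forward read is the first `read_length` bases of the molecule; the
#' reverse read is the reverse complement of the last `read_length` bases
#' (molecules shorter than `read_length` give fully overlapping pairs).
#' Independent substitution errors are applied per base at
#' `substitution_error_rate`. Phred qualities are `qual_high` throughout the
#' forward read; the reverse read declines linearly to `qual_low` over its
#' last `reverse_ramp_len` bases.
#'
#' @param molecules Character vector of molecule sequences.
#' @param config A [simulation_config()].
#' @param ids Optional read identifiers (default `mol000001`, ...).
#' @return Data frame of read pairs: `read_id`, `forward_seq`,
#'   `reverse_seq`, `forward_qual`, `reverse_qual` (qualities as Phred+33
#'   strings).
#' @examples
#' cfg <- simulation_config(n_molecules = 2, rng_seed = 1)
#' sim <- simulate_molecules(cfg)
#' pairs <- molecules_to_read_pairs(sim$sequences, cfg)
#' nchar(pairs$forward_seq)
#' @export
molecules_to_read_pairs <- function(molecules, config, ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  short <- which(nchar(molecules) < 15L)
  if (length(short)) {
    stop("molecule(s) shorter than 15 bp cannot be sequenced as an ",
         "overlapping pair (first offender: index ", short[1L], ")")
  }
  if (is.null(ids)) ids <- sprintf("mol%06d", seq_along(molecules))
  # derived stream so molecule and read randomness are decoupled but both
  # fully determined by rng_seed
  seed2 <- (config$rng_seed + 1000003L) %% .Machine$integer.max
  withr::with_seed(seed2, .reads_impl(molecules, config, ids))
}

.reads_impl <- function(molecules, config, ids) {
  rl <- config$read_length
  n <- length(molecules)
  lens <- nchar(molecules)
  flen <- pmin(rl, lens)
  fwd <- substr(molecules, 1L, flen)
  rev_tpl <- substr(molecules, pmax(1L, lens - rl + 1L), lens)
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(rev_tpl)))

  rate <- config$substitution_error_rate
  nonadj <- config$nonadjacent_errors
  if (rate > 0) {
    for (i in seq_len(n)) {
      fwd[i] <- .apply_substitutions(fwd[i], rate, nonadj)
      rev[i] <- .apply_substitutions(rev[i], rate, nonadj)
    }
  }

  fq <- character(n)
  rq <- character(n)
  for (i in seq_len(n)) {
    fq[i] <- .phred_string(rep.int(config$qual_high, nchar(fwd[i])))
    rq[i] <- .phred_string(.reverse_qual_profile(nchar(rev[i]), config))
  }
  data.frame(read_id = ids, forward_seq = fwd, reverse_seq = rev,
             forward_qual = fq, reverse_qual = rq, stringsAsFactors = FALSE)
}

.reverse_qual_profile <- function(len, config) {
  q <- rep.int(config$qual_high, len)
  ramp <- min(config$reverse_ramp_len, len)
  if (ramp > 1L && config$qual_low < config$qual_high) {
    drop <- seq(config$qual_high, config$qual_low, length.out = ramp)
    q[(len - ramp + 1L):len] <- as.integer(round(drop))
  }
  q
}

#' Write paired reads to FASTQ and read them back
#'
#' Standard 4-line FASTQ with Phred+33 qualities; mate identifiers are
#' identical between the two files and read order is preserved.
#'
#' @param pairs Read-pair data frame as from [molecules_to_read_pairs()].
#' @param r1_path,r2_path Output paths for the forward and reverse mates.
#' @return `write_fastq()` returns the paths invisibly; `read_fastq_pairs()`
#'   returns a read-pair data frame.
#' @examples
#' cfg <- simulation_config(n_molecules = 2, rng_seed = 1)
#' pairs <- molecules_to_read_pairs(simulate_molecules(cfg)$sequences, cfg)
#' r1 <- tempfile(fileext = ".fastq"); r2 <- tempfile(fileext = ".fastq")
#' write_fastq(pairs, r1, r2)
#' identical(read_fastq_pairs(r1, r2), pairs)
#' @export
write_fastq <- function(pairs, r1_path, r2_path) {
  .write_fastq_one(pairs$read_id, pairs$forward_seq, pairs$forward_qual, r1_path)
  .write_fastq_one(pairs$read_id, pairs$reverse_seq, pairs$reverse_qual, r2_path)
  invisible(c(r1_path, r2_path))
}

.write_fastq_one <- function(ids, seqs, quals, path) {
  if (length(ids) == 0L) {
    con <- file(path, "wb"); close(con)
    return(invisible(path))
  }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(quals)
  )
  names(x) <- ids
  .quiet_mcols(Biostrings::writeQualityScaledXStringSet(x, path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- .read_fastq_one(r1_path)
  r2 <- .read_fastq_one(r2_path)
  if (!identical(r1$id, r2$id)) stop("mate identifiers differ between files")
  data.frame(read_id = r1$id, forward_seq = r1$seq, reverse_seq = r2$seq,
             forward_qual = r1$qual, reverse_qual = r2$qual,
             stringsAsFactors = FALSE)
}

.read_fastq_one <- function(path) {
  if (file.size(path) == 0L) {
    return(list(id = character(), seq = character(), qual = character()))
  }
  x <- .quiet_mcols(Biostrings::readQualityScaledDNAStringSet(path))
  list(id = sub("\\s.*$", "", names(x)),
       seq = unname(as.character(x)),
       qual = unname(as.character(Biostrings::quality(x))))
}

#' Write / read the simulation ground-truth table
#'
#' Plain TSV with columns `molecule_id`, `deletion_start`, `deletion_end`,
#' `inserted_sequence`, `is_edited` (coordinates 0-based half-open).
#'
#' @param truth Truth data frame from [simulate_molecules()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  tr$inserted_sequence[is.na(tr$inserted_sequence)] <- ""
  tr
}

#' Simulate a full sample (molecules, reads, optional files)
#'
#' Convenience wrapper: simulates molecules, generates read pairs, and, when
#' `out_prefix` is given, writes `<prefix>_R1.fastq`, `<prefix>_R2.fastq`,
#' `<prefix>_ref.fasta`, `<prefix>_ref.tsv` and `<prefix>_truth.tsv`.
#'
#' @param config A [simulation_config()].
#' @param out_prefix Optional path prefix for on-disk output.
#' @return List with `pairs`, `truth`, `reference`, and (if written) `files`.
#' @export
simulate_sample <- function(config, out_prefix = NULL) {
  sim <- simulate_molecules(config)
  pairs <- molecules_to_read_pairs(sim$sequences, config, ids = sim$truth$molecule_id)
  out <- list(pairs = pairs, truth = sim$truth, reference = config$reference,
              molecules = sim$sequences)
  if (!is.null(out_prefix)) {
    files <- c(r1 = paste0(out_prefix, "_R1.fastq"),
               r2 = paste0(out_prefix, "_R2.fastq"),
               ref_fasta = paste0(out_prefix, "_ref.fasta"),
               ref_annot = paste0(out_prefix, "_ref.tsv"),
               truth = paste0(out_prefix, "_truth.tsv"))
    write_fastq(pairs, files[["r1"]], files[["r2"]])
    write_amplicon_reference(config$reference, files[["ref_fasta"]], files[["ref_annot"]])
    write_truth(sim$truth, files[["truth"]])
    out$files <- files
  }
  out
}
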