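# End-to-end driver: FASTQ (or in-memory pairs) -> stitched observed
# sequences -> per-read indel calls -> sample editing profile.

#' Run the full editing-outcome pipeline on one sample
#'
#' Stitches all read pairs, applies the terminal wild-type anchor filter,
#' calls forward/reverse breakpoints and indel regions for every observed
#' sequence, and aggregates the sample editing profile.
#'
#' @param pairs Read-pair data frame (see [molecules_to_read_pairs()]), or
#'   `NULL` if `r1`/`r2` are given.
#' @param ref An [amplicon_reference()].
#' @param r1,r2 Optional paths to paired FASTQ files (used when `pairs` is
#'   `NULL`).
#' @param sample_id Sample identifier carried into the profile.
#' @param min_overlap,max_overlap_mismatch_frac Stitching parameters (see
#'   [stitch_pair()]).
#' @param anchor_len,max_anchor_mismatches Anchor filter parameters (see
#'   [check_wildtype_anchor()]).
#' @param artifact_min_len Long-region artifact threshold (see
#'   [call_indel()]).
#' @param n_top Patterns retained in the profile's pattern table.
#' @return A list with `stitched` (stitch results), `calls` (per-read
#'   calls) and `profile` (an [editing_profile()]).
#' @examples
#' cfg <- simulation_config(n_molecules = 50, rng_seed = 3)
#' sample <- simulate_sample(cfg)
#' res <- run_pipeline(sample$pairs, cfg$reference)
#' res$profile
#' @export
run_pipeline <- function(pairs = NULL, ref, r1 = NULL, r2 = NULL,
                         sample_id = "sample1",
                         min_overlap = 15L, max_overlap_mismatch_frac = 0.1,
                         anchor_len = 40L, max_anchor_mismatches = 0L,
                         artifact_min_len = 25L, n_top = 20L) {
  if (is.null(pairs)) {
    if (is.null(r1) || is.null(r2)) stop("supply either `pairs` or `r1` and `r2`")
    pairs <- read_fastq_pairs(r1, r2)
  }
  stitched <- stitch_pairs(pairs, ref, min_overlap = min_overlap,
                           max_overlap_mismatch_frac = max_overlap_mismatch_frac,
                           anchor_len = anchor_len,
                           max_anchor_mismatches = max_anchor_mismatches)
  calls <- call_indels(stitched, ref, artifact_min_len = artifact_min_len)
  profile <- editing_profile(calls, ref, sample_id = sample_id, n_top = n_top)
  list(stitched = stitched, calls = calls, profile = profile)
}
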