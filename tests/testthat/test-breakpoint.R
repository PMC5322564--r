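test_that("breakpoint scans reproduce the defining examples", {
  ref <- "AAAAAAAA"
  expect_identical(forward_breakpoint(ref, ref), NA_integer_)
  expect_identical(reverse_breakpoint(ref, ref), NA_integer_)
  # two consecutive mismatches at offsets 4,5
  expect_identical(forward_breakpoint("AAAACCAA", ref), 4L)
  expect_identical(reverse_breakpoint("AAAACCAA", ref), 6L)
  # an isolated mismatch never triggers a breakpoint
  expect_identical(forward_breakpoint("AACAAAAA", ref), NA_integer_)
  expect_identical(reverse_breakpoint("AACAAAAA", ref), NA_integer_)
  expect_error(forward_breakpoint("", ref), "empty")
})

test_that("reverse breakpoint is the reflected forward breakpoint", {
  rev_str <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  withr::with_seed(53, {
    for (i in 1:200) {
      pair <- random_obs_pair()
      r <- reverse_breakpoint(pair$obs, pair$ref)
      f_rev <- forward_breakpoint(rev_str(pair$obs), rev_str(pair$ref))
      expect_identical(r, if (is.na(f_rev)) NA_integer_ else
        nchar(pair$ref) - f_rev)
    }
  })
})

test_that("scanning implementation matches the brute-force oracle", {
  withr::with_seed(59, {
    for (i in 1:1000) {
      pair <- random_obs_pair()
      expect_identical(forward_breakpoint(pair$obs, pair$ref),
                       oracle_forward(pair$obs, pair$ref))
      expect_identical(reverse_breakpoint(pair$obs, pair$ref),
                       oracle_reverse(pair$obs, pair$ref))
    }
  })
})

test_that("N bases count as mismatches in the scans", {
  ref <- "ACGTACGTAC"
  expect_identical(forward_breakpoint("ACNNACGTAC", ref), 2L)
  expect_identical(forward_breakpoint("ACNTACGTAC", ref), NA_integer_)
})

test_that("a clean interior deletion is called exactly", {
  # flanks built so the deletion mismatches immediately from both sides
  ref <- paste0(strrep("A", 60), "CCCCCC", strrep("T", 60))
  obs <- paste0(strrep("A", 60), strrep("T", 60))
  call <- call_indel(obs, ref)
  expect_identical(call$status, "edited")
  expect_identical(call$deletion_start, 60L)
  expect_identical(call$deletion_end, 66L)
  expect_identical(call$inserted_sequence, "")
  expect_identical(call$length_difference, -6L)
})

test_that("a clean insertion at an interior junction is recovered", {
  ref <- paste0(strrep("A", 63), strrep("T", 57))
  obs <- paste0(strrep("A", 63), "GATC", strrep("T", 57))
  call <- call_indel(obs, ref)
  expect_identical(call$status, "edited")
  expect_identical(call$inserted_sequence, "GATC")
  expect_true(is.na(call$deletion_start))
  expect_identical(call$length_difference, 4L)
})

test_that("identical and isolated-mismatch sequences are wild-type-like", {
  ref <- tp53_amplicon()
  expect_identical(call_indel(ref$sequence, ref)$status, "wildtype_like")
  # scattered non-adjacent substitutions never produce an edited call
  withr::with_seed(61, {
    for (i in 1:50) {
      obs <- add_substitution_errors(ref$sequence, 0.01, nonadjacent = TRUE)
      expect_identical(call_indel(obs, ref)$status, "wildtype_like")
    }
  })
})

test_that("anchor failures short-circuit breakpoint calling", {
  ref <- tp53_amplicon()
  call <- call_indel(ref$sequence, ref, anchor_ok = FALSE)
  expect_identical(call$status, "unanchored")
  expect_true(is.na(call$forward_breakpoint))
})

test_that("length identity holds for every non-artifact call", {
  cfg <- simulation_config(n_molecules = 400, substitution_error_rate = 0.003,
                           rng_seed = 67)
  s <- simulate_sample(cfg)
  res <- run_pipeline(s$pairs, cfg$reference)
  calls <- res$calls[!(res$calls$status %in% c("unanchored", "artifact")), ]
  dl <- ifelse(is.na(calls$deletion_start), 0L,
               calls$deletion_end - calls$deletion_start)
  expect_equal(calls$length_difference, nchar(calls$inserted_sequence) - dl)
  # and length_difference is literally the observed-length change
  seq_of <- setNames(res$stitched$sequence, res$stitched$read_id)
  expect_equal(calls$length_difference,
               unname(nchar(seq_of[calls$read_id])) - nchar(cfg$reference$sequence))
})

test_that("reconciled boundary calls recover clean deletions near the truth", {
  # clean fixed-length deletions whose flanks force breakpoint overshoot
  cfg <- simulation_config(
    n_molecules = 300, edited_fraction = 1,
    deletion_length_distribution = list(name = "fixed", length = 6),
    insertion_probability = 0, substitution_error_rate = 0, rng_seed = 71)
  s <- simulate_sample(cfg)
  res <- run_pipeline(s$pairs, cfg$reference)
  ed <- res$calls[res$calls$status == "edited", ]
  expect_identical(nrow(ed), 300L)
  # the deletion length is recovered exactly even when the raw breakpoints
  # crossed and had to be reconciled
  expect_true(all(ed$deletion_end - ed$deletion_start == 6L))
  expect_true(all(ed$inserted_sequence == ""))
  # the called interval sits within the scan-tolerance window of the truth
  truth <- s$truth[match(ed$read_id, s$truth$molecule_id), ]
  expect_true(all(abs(ed$deletion_start - truth$deletion_start) <= 10L))
  # the raw scans never stopped inside the called flanks: the reconciled
  # interval is contained in [forward scan stop's left, reverse stop's right]
  for (i in seq_len(nrow(ed))) {
    obs <- res$stitched$sequence[res$stitched$read_id == ed$read_id[i]]
    f_raw <- oracle_forward(obs, cfg$reference$sequence)
    expect_lte(ed$deletion_start[i], f_raw)
  }
})

test_that("long paired insertion/deletion regions are flagged as artifacts", {
  ref <- tp53_amplicon()
  # a molecule whose centre is replaced by 30 bp of unrelated sequence:
  # 40 bp deletion with a 30 bp insertion, both over the artifact threshold
  withr::with_seed(73, junk <- random_dna(30))
  obs <- paste0(substr(ref$sequence, 1, 80), junk,
                substr(ref$sequence, 121, 200))
  call <- call_indel(obs, ref)
  expect_identical(call$status, "artifact")
  expect_gte(call$deletion_end - call$deletion_start, 25L)
  expect_gte(nchar(call$inserted_sequence), 25L)
})
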