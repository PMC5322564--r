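test_that("indel efficiency counts exactly the length-changing calls", {
  all_wt <- do.call(rbind, replicate(5, make_call(), simplify = FALSE))
  expect_equal(indel_efficiency(all_wt), 0)

  calls <- rbind(
    do.call(rbind, replicate(600, make_call("edited", ds = 97L, de = 103L),
                             simplify = FALSE)),
    do.call(rbind, replicate(400, make_call(), simplify = FALSE)))
  expect_equal(indel_efficiency(calls), 60)

  expect_error(indel_efficiency(all_wt[0, ]), "undefined")
})

test_that("per-position fractions follow deletion spans and insertion junctions", {
  ref <- tp53_amplicon()
  all_wt <- do.call(rbind, replicate(4, make_call(), simplify = FALSE))
  pp <- per_position_edit_fraction(all_wt, ref)
  expect_true(all(pp$fraction == 0))

  dels <- do.call(rbind, replicate(3, make_call("edited", ds = 60L, de = 66L),
                                   simplify = FALSE))
  pp <- per_position_edit_fraction(dels, ref)
  expect_true(all(pp$fraction[pp$position %in% 60:65] == 1))
  expect_true(all(pp$fraction[!(pp$position %in% 60:65)] == 0))

  # a single insertion marks the two reference bases flanking the junction
  one_ins <- rbind(make_call("edited", ins = "GATC", f = 63L, r = 63L),
                   make_call(), make_call(), make_call())
  pp <- per_position_edit_fraction(one_ins, ref)
  expect_equal(pp$fraction[pp$position %in% c(62, 63)], c(0.25, 0.25))
  expect_true(all(pp$fraction[!(pp$position %in% c(62, 63))] == 0))
  # one-sided adjacency marks only the base at the forward breakpoint
  pp_r <- per_position_edit_fraction(one_ins, ref, adjacency = "right")
  expect_equal(sum(pp_r$fraction > 0), 1L)
  expect_equal(pp_r$fraction[pp_r$position == 63], 0.25)
})

test_that("length histograms give each call's deletion and insertion mass", {
  all_wt <- do.call(rbind, replicate(10, make_call(), simplify = FALSE))
  dh <- deletion_length_hist(all_wt)
  expect_equal(dh, data.frame(length = 0L, fraction = 1))

  # one call with a 3 bp deletion AND a 3 bp insertion among 10 calls
  # contributes 0.1 to both histograms
  calls <- rbind(make_call("edited", ds = 60L, de = 63L, ins = "TAG", f = 60L),
                 do.call(rbind, replicate(9, make_call(), simplify = FALSE)))
  dh <- deletion_length_hist(calls)
  ih <- insertion_length_hist(calls)
  expect_equal(dh$fraction[dh$length == 3], 0.1)
  expect_equal(ih$fraction[ih$length == 3], 0.1)
  expect_equal(dh$fraction[dh$length == 0], 0.9)
  expect_equal(sum(dh$fraction), 1)
  expect_equal(sum(ih$fraction), 1)
})

test_that("a length-neutral edit is invisible to efficiency but not histograms", {
  calls <- rbind(make_call("edited", ds = 60L, de = 63L, ins = "TAG", f = 60L),
                 do.call(rbind, replicate(9, make_call(), simplify = FALSE)))
  expect_equal(calls$length_difference[1], 0L)
  expect_equal(indel_efficiency(calls), 0)
  expect_equal(deletion_length_hist(calls)$fraction[2], 0.1)
  expect_equal(insertion_length_hist(calls)$fraction[2], 0.1)
  # and it still marks its positions as edited
  pp <- per_position_edit_fraction(calls, tp53_amplicon())
  expect_equal(pp$fraction[pp$position == 60], 0.1)
})

test_that("deletion pileup counts spanning intervals position by position", {
  ref <- tp53_amplicon()
  none <- do.call(rbind, replicate(3, make_call(), simplify = FALSE))
  expect_true(all(deletion_pileup(none, ref)$count == 0))

  two <- rbind(make_call("edited", ds = 10L, de = 14L),
               make_call("edited", ds = 12L, de = 16L))
  pu <- deletion_pileup(two, ref)
  expect_equal(pu$count[pu$position %in% 10:15], c(1L, 1L, 2L, 2L, 1L, 1L))
  expect_true(all(pu$count <= 2L))
})

test_that("per-position edited fraction dominates the deletion pileup rate", {
  cfg <- simulation_config(n_molecules = 500, rng_seed = 83,
                           substitution_error_rate = 0)
  s <- simulate_sample(cfg)
  res <- run_pipeline(s$pairs, cfg$reference)
  pp <- per_position_edit_fraction(res$calls, cfg$reference)
  pu <- deletion_pileup(res$calls, cfg$reference)
  n <- sum(!(res$calls$status %in% c("unanchored", "artifact")))
  expect_true(all(pp$fraction >= pu$count / n - 1e-12))
})

test_that("pattern ranking matches a count-and-sort oracle", {
  ref <- tp53_amplicon()
  # two patterns, counts 30 and 70: the 70-count pattern ranks first
  calls <- rbind(
    do.call(rbind, replicate(30, make_call("edited", ds = 95L, de = 101L),
                             simplify = FALSE)),
    do.call(rbind, replicate(70, make_call("edited", ds = 97L, de = 103L),
                             simplify = FALSE)))
  tab <- top_patterns(calls, ref)
  expect_equal(tab$total, c(70L, 30L))
  expect_equal(tab$deletion_start, c(97L, 95L))

  # 25 distinct patterns with known counts, n_top = 20: exactly 20 rows and
  # no excluded pattern outranks an included one
  withr::with_seed(89, counts <- sample(1:40, 25, replace = TRUE))
  calls <- do.call(rbind, lapply(seq_len(25), function(k) {
    do.call(rbind, replicate(counts[k],
      make_call("edited", ds = 40L + k, de = 46L + k), simplify = FALSE))
  }))
  tab <- top_patterns(calls, ref, n_top = 20L)
  expect_identical(nrow(tab), 20L)
  oracle_sorted <- sort(counts, decreasing = TRUE)
  expect_equal(tab$total, oracle_sorted[1:20])
  expect_true(min(tab$total) >= max(oracle_sorted[21:25]))

  expect_error(top_patterns(calls, ref, n_top = 0L), "n_top")
})

test_that("pattern table renders insertions and keeps per-sample counts", {
  ref <- tp53_amplicon()
  long_ins <- strrep("A", 30)
  calls <- rbind(
    make_call("edited", ds = 97L, de = 103L, ins = "TT", f = 97L,
              sample_id = "s1"),
    make_call("edited", ds = 97L, de = 103L, ins = "TT", f = 97L,
              sample_id = "s2"),
    make_call("artifact", ds = 80L, de = 120L, ins = long_ins, f = 80L,
              ldiff = -10L, sample_id = "s1"))
  tab <- top_patterns(calls, ref)
  expect_identical(nrow(tab), 2L)
  # short insertions are rendered literally, long ones as a bracketed length
  expect_identical(tab$insertion_rendered, c("TT", "[30]"))
  expect_equal(tab$count.s1, c(1L, 1L))
  expect_equal(tab$count.s2, c(1L, 0L))
  # dashes across the deletion in the alignment line
  expect_match(tab$alignment[1], "\\{TT\\}------")

  # single unique pattern: one row carrying the full count
  one <- do.call(rbind, replicate(7, make_call("edited", ds = 97L, de = 103L),
                                  simplify = FALSE))
  tab1 <- top_patterns(one, ref)
  expect_identical(nrow(tab1), 1L)
  expect_equal(tab1$total, 7L)
})

test_that("editing profile bundles consistent sample summaries", {
  cfg <- simulation_config(n_molecules = 300, rng_seed = 97)
  s <- simulate_sample(cfg)
  res <- run_pipeline(s$pairs, cfg$reference, sample_id = "demo")
  prof <- res$profile
  expect_s3_class(prof, "editing_profile")
  expect_identical(prof$sample_id, "demo")
  expect_true(prof$indel_efficiency >= 0 && prof$indel_efficiency <= 100)
  expect_true(all(prof$per_position$fraction >= 0 &
                  prof$per_position$fraction <= 1))
  expect_equal(sum(prof$deletion_length_hist$fraction), 1)
  expect_equal(sum(prof$insertion_length_hist$fraction), 1)
  expect_output(print(prof), "indel efficiency")

  dir <- withr::local_tempdir()
  write_profile(prof, file.path(dir, "demo"))
  expect_true(file.exists(file.path(dir, "demo_per_position.tsv")))
  back <- utils::read.delim(file.path(dir, "demo_per_position.tsv"))
  expect_equal(back$fraction, prof$per_position$fraction)
})
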