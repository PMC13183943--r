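test_that("quality filter applies the unqualified-fraction and mean rules", {
  pol <- quality_policy()
  expect_true(quality_filter(strrep("A", 50), rep(30L, 50), pol)$pass)
  f <- quality_filter(strrep("A", 50), rep(19L, 50), pol)
  expect_false(f$pass)
  # 31% of bases below Q20 fails the -u rule even though the mean passes
  qual <- c(rep(10L, 31), rep(40L, 69))
  expect_equal(mean(qual), 30.7)
  f <- quality_filter(strrep("A", 100), qual, pol)
  expect_false(f$pass)
  expect_equal(f$reason, "unqualified")
  # 30% exactly is allowed
  expect_true(quality_filter(strrep("A", 100), c(rep(10L, 30), rep(40L, 70)),
                             pol)$pass)
  expect_error(quality_filter("ACGT", rep(30L, 3), pol), "length")
})

test_that("raising the mean-quality threshold never converts a fail into a pass", {
  withr::with_seed(11, {
    for (i in 1:20) {
      qual <- sample(2:41, 80, replace = TRUE)
      seq <- strrep("A", 80)
      verdicts <- vapply(seq(10, 40, by = 2), function(e) {
        quality_filter(seq, qual, quality_policy(min_avg_q = e))$pass
      }, logical(1))
      expect_true(all(diff(verdicts) <= 0))  # once failing, stays failing
    }
  })
})

test_that("an error-free pair merges back into the 258-nt insert with 42-bp overlap", {
  d <- cd_clim_design()
  insert <- build_reference_amplicon(d, c("CCGGTA", "AATCGC"))
  p <- make_clean_pair(insert, d)
  m <- merge_pair(p$seq1, p$qual1, p$seq2, p$qual2)
  expect_equal(m$overlap, 42L)
  expect_equal(m$seq, insert)
  expect_equal(length(m$qual), 258L)
})

test_that("fully overlapping identical reads merge to themselves", {
  s <- "ACGTTGCAACGGTTAACCGGTACGATCGAT"
  m <- merge_pair(s, rep(30L, nchar(s)), climkit:::.revcomp(s),
                  rep(30L, nchar(s)))
  expect_equal(m$overlap, nchar(s))
  expect_equal(m$seq, s)
})

test_that("heavily mismatched overlaps and empty reads are rejected", {
  d <- cd_clim_design()
  insert <- build_reference_amplicon(d, c("CCGGTA", "AATCGC"))
  p <- make_clean_pair(insert, d)
  # corrupt half of r1's 42-base overlap tail
  tail42 <- substr(p$seq1, 109, 150)
  flip <- chartr("ACGT", "CATG", substr(tail42, 1, 21))
  seq1_bad <- paste0(substr(p$seq1, 1, 108), flip, substr(tail42, 22, 42))
  m <- merge_pair(seq1_bad, p$qual1, p$seq2, p$qual2, max_mismatch_frac = 0.25)
  expect_equal(m$reason, "mismatch")
  expect_equal(merge_pair("", integer(0), "ACGT", rep(30L, 4))$reason, "empty")
})

test_that("overlap consensus keeps the higher-quality base, read 1 on ties", {
  d <- cd_clim_design()
  insert <- build_reference_amplicon(d, c("CCGGTA", "AATCGC"))
  p <- make_clean_pair(insert, d)
  # introduce a disagreement at insert position 120 (inside the overlap)
  wrong <- chartr("ACGT", "CATG", substr(p$seq1, 120, 120))
  seq1_err <- p$seq1
  substr(seq1_err, 120, 120) <- wrong
  # r2 higher quality: the correct base wins
  m <- merge_pair(seq1_err, rep(20L, 150), p$seq2, rep(35L, 150))
  expect_equal(substr(m$seq, 120, 120), substr(insert, 120, 120))
  expect_equal(m$qual[120], 35L)
  # equal quality: read 1 wins
  m2 <- merge_pair(seq1_err, rep(30L, 150), p$seq2, rep(30L, 150))
  expect_equal(substr(m2$seq, 120, 120), wrong)
})

test_that("filtering and merging commute on a clean pair", {
  d <- cd_clim_design()
  insert <- build_reference_amplicon(d, c("TTAGCA", "GGCATC"))
  p <- make_clean_pair(insert, d, q = 33L)
  pol <- quality_policy()
  expect_true(quality_filter(p$seq1, p$qual1, pol)$pass)
  expect_true(quality_filter(p$seq2, p$qual2, pol)$pass)
  m <- merge_pair(p$seq1, p$qual1, p$seq2, p$qual2)
  expect_true(quality_filter(m$seq, m$qual, pol)$pass)
  expect_equal(m$seq, insert)
})

test_that("process_reads accounts for every input pair", {
  d <- cd_clim_design()
  dir <- withr::local_tempdir()
  sp <- simulation_spec(depth_t0 = 1500, depth_t1 = 1500,
                        per_base_error = 0.002, seed = 5)
  sim <- simulate_library(d, sp, dir)
  pr <- process_reads(sim$metadata$fastq1[1], sim$metadata$fastq2[1])
  r <- pr$report
  expect_equal(r$pairs_in, 1500L)
  expect_equal(r$fail_quality + r$merged + r$reject_no_overlap +
                 r$reject_mismatch, r$pairs_in)
  expect_equal(length(pr$seq), r$merged)
})
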