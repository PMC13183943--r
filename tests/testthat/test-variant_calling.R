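test_that("parse_insert demands exact length and anchors", {
  d <- cd_clim_design()
  insert <- build_reference_amplicon(d, c("ACACAC", "GTGTGT"))
  p <- parse_insert(insert, d)
  expect_true(p$ok)
  expect_equal(p$reporter, d$wt_reporter)
  # 1-nt deletion anywhere -> presumed indel
  del <- paste0(substr(insert, 1, 99), substr(insert, 101, 258))
  expect_equal(parse_insert(del, d)$reason, "indel")
  # anchor5 TAG -> TAC
  bad <- insert
  substr(bad, 9, 9) <- "C"
  expect_equal(parse_insert(bad, d)$reason, "anchor")
})

test_that("classification separates WT, on-site singles, offsite and multi hits", {
  d <- cd_clim_design()
  expect_equal(classify_reporter(d$wt_reporter, d)$class, "wt")
  # residue 75 = reporter codon 70; alanine codon GCT
  r <- mutate_reporter(d, list(`70` = "GCT"))
  cl <- classify_reporter(r, d)
  expect_equal(cl[c("class", "position", "codon", "aa")],
               list(class = "single", position = 75L, codon = "GCT", aa = "A"))
  expect_true(cl$is_nnk)
  # amber stop at residue 50 (reporter codon 45) is a counted variant
  cl <- classify_reporter(mutate_reporter(d, list(`45` = "TAG")), d)
  expect_equal(cl$aa, "*")
  # two mutated codons -> discard
  r2 <- mutate_reporter(d, list(`40` = "GCG", `60` = "CCG"))
  expect_equal(classify_reporter(r2, d)$reason, "multi")
  # single mismatch in the GFP linker (codon 5) -> offsite
  r3 <- mutate_reporter(d, list(`5` = "AAA"))
  expect_equal(classify_reporter(r3, d)$reason, "offsite")
  # non-NNK single is kept but flagged
  cl <- classify_reporter(mutate_reporter(d, list(`70` = "GCA")), d)
  expect_equal(cl$class, "single")
  expect_false(cl$is_nnk)
})

test_that("count_variants conserves reads across classes exactly", {
  d <- cd_clim_design()
  reps <- c(d$wt_reporter,
            mutate_reporter(d, list(`70` = "GCT")),
            mutate_reporter(d, list(`70` = "GCT")),
            mutate_reporter(d, list(`45` = "TAG")),
            mutate_reporter(d, list(`5` = "AAA")),
            mutate_reporter(d, list(`40` = "GCG", `60` = "CCG")))
  seqs <- vapply(reps, function(r) insert_from_reporter(d, r), character(1))
  seqs <- c(seqs, substr(seqs[1], 1, 257), sub("TAG", "TAC", seqs[1]))
  vct <- count_variants(seqs, d, "s1")
  expect_equal(vct$reads_in, 8L)
  expect_equal(vct$wt_count + sum(vct$counts$count) + sum(vct$discards), 8L)
  expect_equal(unname(vct$discards[c("indel", "anchor", "multi", "offsite")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(vct$counts$count[vct$counts$position == 75 &
                                  vct$counts$codon == "GCT"], 2L)
})

test_that("error-free synthetic counts equal the simulator's truth exactly", {
  d <- cd_clim_design()
  dir <- withr::local_tempdir()
  sp <- simulation_spec(depth_t0 = 4000, depth_t1 = 4000,
                        per_base_error = 0, seed = 9)
  sim <- simulate_library(d, sp, dir)
  for (i in c(1L, 4L)) {
    sid <- sim$metadata$sample_id[i]
    pr <- process_reads(sim$metadata$fastq1[i], sim$metadata$fastq2[i])
    vct <- count_variants(pr$seq, d, sid)
    truth <- sim$truth_counts[sim$truth_counts$sample_id == sid, ]
    expect_equal(sum(vct$discards), 0L)
    expect_equal(vct$wt_count, sum(truth$count[truth$class == "wt"]))
    tv <- truth[truth$class == "single" & truth$count > 0, ]
    merged <- merge(vct$counts, tv, by = c("position", "codon"))
    expect_equal(nrow(merged), nrow(tv))
    expect_equal(nrow(merged), nrow(vct$counts))
    expect_equal(merged$count.x, merged$count.y)
  }
})

test_that("at 0.1% per-base error almost all classified reads hit their true variant", {
  d <- cd_clim_design()
  withr::with_seed(31, {
    # 3000 reads from one known single-variant molecule class per batch
    pool_codons <- c("GCT", "TGG", "AAG", "CCG")
    ok <- 0L; classified <- 0L
    for (cd in pool_codons) {
      rep_seq <- mutate_reporter(d, list(`70` = cd))
      hex <- replicate(750, paste(sample(c("A", "C", "G", "T"), 12,
                                         replace = TRUE), collapse = ""))
      inserts <- paste0(substr(hex, 1, 6), d$anchor5, rep_seq, d$anchor3,
                        substr(hex, 7, 12))
      inserts <- climkit:::.apply_errors(inserts, 258L, 0.001)
      vct <- count_variants(inserts, d)
      n_class <- vct$wt_count + sum(vct$counts$count)
      hit <- vct$counts$count[vct$counts$position == 75 &
                                vct$counts$codon == cd]
      classified <- classified + n_class
      ok <- ok + sum(hit)
    }
    expect_gte(ok / classified, 0.97)
  })
})
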