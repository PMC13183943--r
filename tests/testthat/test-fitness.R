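make_vct <- function(design, wt, triples, sample_id = "s") {
  counts <- tibble::tibble(
    position = vapply(triples, `[[`, 0L, 1),
    codon = vapply(triples, `[[`, "", 2),
    count = vapply(triples, `[[`, 0L, 3))
  counts$aa <- translate_codons(counts$codon)
  counts$is_nnk <- substr(counts$codon, 3, 3) %in% c("G", "T")
  structure(list(sample_id = sample_id, wt_count = wt,
                 counts = counts[, c("position", "codon", "aa", "is_nnk",
                                     "count")],
                 discards = c(indel = 0L), reads_in = wt + sum(counts$count)),
            class = "variant_count_table")
}

test_that("rpm normalizes to one million over WT plus variants", {
  d <- cd_clim_design()
  v <- make_vct(d, 0L, list(list(75L, "GCT", 1000L)))
  r <- rpm(v)
  expect_equal(r$rpm[r$aa == "A"], 1e6)
  v2 <- make_vct(d, 0L, list(list(75L, "GCT", 250L), list(50L, "TGG", 750L)))
  r2 <- rpm(v2)
  expect_equal(sort(r2$rpm[!is.na(r2$position)]), c(2.5e5, 7.5e5))
  # synonymous codons pool per amino acid by default
  v3 <- make_vct(d, 100L, list(list(75L, "GCT", 40L), list(75L, "GCG", 60L)))
  r3 <- rpm(v3)
  expect_equal(r3$rpm[which(r3$aa == "A")], 100 / 200 * 1e6)
  expect_equal(sum(r3$rpm), 1e6, tolerance = 1e-6)
  expect_error(rpm(make_vct(d, 0L, list())), "empty")
})

test_that("growth rate follows log2(CFU ratio x RPM ratio) per hour", {
  expect_equal(growth_rate(500, 500, 1e7, 1e7, 5), 0)
  expect_equal(growth_rate(100, 100, 1e7, 4e7, 2), 1.0)
  expect_equal(growth_rate(1000, 500, 1e7, 8e7, 3), 2 / 3)
  expect_true(is.na(growth_rate(0, 100, 1e7, 1e7, 1)))
  expect_true(is.na(growth_rate(100, 0, 1e7, 1e7, 1)))
  expect_error(growth_rate(1, 1, 0, 1e7, 1), "CFU")
  expect_error(growth_rate(1, 1, 1e7, 1e7, 0), "hours")
})

test_that("relative fitness is the ratio of growth rates, undefined for a non-growing reference", {
  expect_equal(relative_fitness(0.5, 0.5), 1.0)
  expect_equal(relative_fitness(0, 0.5), 0.0)
  expect_true(is.na(relative_fitness(0.5, 0)))
  expect_true(is.na(relative_fitness(0.5, -0.2)))
  expect_true(is.na(relative_fitness(NA_real_, 0.5)))
})

test_that("scaling all counts in a sample leaves growth rates unchanged", {
  d <- cd_clim_design()
  base <- list(list(75L, "GCT", 40L), list(50L, "TGG", 160L))
  scaled <- lapply(base, function(x) list(x[[1]], x[[2]], x[[3]] * 7L))
  r1 <- rpm(make_vct(d, 300L, base))
  r2 <- rpm(make_vct(d, 2100L, scaled))
  expect_equal(r1$rpm, r2$rpm)
  g1 <- growth_rate(r1$rpm, rev(r1$rpm), 1e7, 3e7, 4)
  g2 <- growth_rate(r2$rpm, rev(r2$rpm), 1e7, 3e7, 4)
  expect_equal(g1, g2)
})

test_that("replicate aggregation averages passing variants and masks the rest", {
  rec <- tibble::tibble(
    replicate = c(1L, 2L, 1L, 2L),
    position = c(75L, 75L, 50L, 50L),
    aa = c("A", "A", "W", "W"),
    relative_fitness = c(0.4, 0.6, 0.9, 1.1),
    pass_filter = c(TRUE, TRUE, TRUE, FALSE))
  agg <- aggregate_fitness(rec)
  expect_equal(agg$mean_fitness[agg$position == 75], 0.5)
  expect_true(is.na(agg$mean_fitness[agg$position == 50]))  # masked, not zeroed
})

test_that("the read filter masks variants below eight t0 reads in either condition", {
  d <- cd_clim_design()
  mk <- function(n75) make_vct(d, 500L, list(list(75L, "GCT", n75),
                                             list(50L, "TGG", 50L)))
  tabs <- list(
    r1_spc_t0 = mk(7L), r1_spc_t1 = mk(20L),
    r1_nospc_t0 = mk(30L), r1_nospc_t1 = mk(30L))
  md <- tibble::tibble(
    sample_id = names(tabs), replicate = 1L,
    condition = rep(c("spc", "nospc"), each = 2),
    timepoint = rep(c("t0", "t1"), 2),
    cfu = 1e7, culture_hours = 3)
  rec <- dms_fitness(tabs, md, min_reads = 8L)
  expect_false(rec$pass_filter[rec$position == 75 & !is.na(rec$position)])
  expect_true(rec$pass_filter[rec$position == 50 & !is.na(rec$position)])
  agg <- aggregate_fitness(rec)
  expect_true(is.na(agg$mean_fitness[agg$position == 75 & !is.na(agg$position)]))
})

test_that("when all variants share the WT growth rate, fitness centres on one", {
  d <- cd_clim_design()
  dir <- withr::local_tempdir()
  flat <- tidyr::expand_grid(
    position = d$residues,
    aa = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*"))
  flat$fitness <- 1.0
  sp <- simulation_spec(true_relative_fitness = flat, wt_fitness = 1.0,
                        depth_t0 = 3e4, depth_t1 = 3e4,
                        per_base_error = 0, replicates = 1L, seed = 13)
  sim <- simulate_library(d, sp, dir)
  tabs <- lapply(seq_len(nrow(sim$metadata)), function(i) {
    pr <- process_reads(sim$metadata$fastq1[i], sim$metadata$fastq2[i])
    count_variants(pr$seq, d, sim$metadata$sample_id[i])
  })
  names(tabs) <- sim$metadata$sample_id
  rec <- dms_fitness(tabs, sim$metadata)
  vals <- rec$relative_fitness[rec$pass_filter & !is.na(rec$position)]
  expect_gt(length(vals), 500)
  expect_equal(mean(vals), 1.0, tolerance = 0.02)
  expect_equal(unname(quantile(vals, 0.5)), 1.0, tolerance = 0.05)
})
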