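#' Simulation settings for a synthetic DMS selection experiment
#'
#' Describes the selection scheme the generator emulates: an NNK
#' single-codon variant library grown with and without spectinomycin, in
#' replicate, sequenced at two timepoints. Relative fitness `r` maps to the
#' selective growth rate as `g_spc = r * base_growth_rate`, while all
#' variants share `base_growth_rate` without selection, matching the
#' definition of relative fitness as a ratio of growth rates.
#'
#' @param true_relative_fitness Optional tibble (`position`, `aa`,
#'   `fitness`) of planted relative-fitness values covering every mutable
#'   position x amino acid (21 including stop). When `NULL`, values are
#'   drawn uniformly on \[0, 1.2\] from `seed`, except that substitutions
#'   reproducing the wild-type amino acid inherit `wt_fitness` (a
#'   synonymous change cannot alter the phenotype).
#' @param wt_fitness Relative fitness of the wild-type protein (default
#'   0.2: stable arrest blocks the resistance gene, so growth under
#'   selection is poor).
#' @param base_growth_rate Growth rate without selection, log2 units/hour
#'   (default 1.0: one doubling per hour).
#' @param culture_hours Time between t0 and t1 (default 3, to mid-log).
#' @param depth_t0,depth_t1 Read pairs per sample at each timepoint.
#' @param cfu_t0 Colony-forming units at t0 (default 1e7).
#' @param cfu_t1 Optional named override; by default derived from the
#'   planted growth (`cfu_t0 * sum(f0 * 2^(g h))` per condition) so the
#'   CFU ratio in the metadata is consistent with the planted truth.
#' @param per_base_error Per-base substitution error probability.
#' @param replicates Number of biological replicates (default 2).
#' @param seed Integer seed; every stochastic draw derives from it.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(true_relative_fitness = NULL, wt_fitness = 0.2,
                            base_growth_rate = 1.0, culture_hours = 3,
                            depth_t0 = 2e5, depth_t1 = 2e5, cfu_t0 = 1e7,
                            cfu_t1 = NULL, per_base_error = 0.001,
                            replicates = 2L, seed = 1L) {
  stopifnot(per_base_error >= 0, per_base_error <= 1,
            depth_t0 >= 0, depth_t1 >= 0, cfu_t0 > 0,
            culture_hours > 0, base_growth_rate > 0, replicates >= 1,
            wt_fitness >= 0)
  if (!is.null(true_relative_fitness)) {
    stopifnot(all(c("position", "aa", "fitness") %in%
                    names(true_relative_fitness)),
              all(true_relative_fitness$fitness >= 0))
  }
  structure(list(true_relative_fitness = true_relative_fitness,
                 wt_fitness = wt_fitness,
                 base_growth_rate = base_growth_rate,
                 culture_hours = culture_hours,
                 depth_t0 = as.integer(depth_t0),
                 depth_t1 = as.integer(depth_t1),
                 cfu_t0 = cfu_t0, cfu_t1 = cfu_t1,
                 per_base_error = per_base_error,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

NNK_CODONS <- as.vector(outer(
  as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
  c("G", "T"), paste0))

# One row per library molecule class: every NNK codon at every mutable
# position. Codons identical to the wild-type codon are the WT class.
.variant_pool <- function(design) {
  pool <- tidyr::expand_grid(slot = seq_along(design$mutable_codons),
                             codon = NNK_CODONS)
  pool$position <- design$residues[pool$slot]
  pool$codon_idx <- design$mutable_codons[pool$slot]
  pool$wt_codon <- design$wt_codons[pool$codon_idx]
  pool$aa <- translate_codons(pool$codon)
  pool$class <- ifelse(pool$codon == pool$wt_codon, "wt", "single")
  # the reporter sequence carried by each molecule class
  pool$reporter <- vapply(seq_len(nrow(pool)), function(i) {
    r <- design$wt_reporter
    substr(r, 3L * pool$codon_idx[i] - 2L, 3L * pool$codon_idx[i]) <- pool$codon[i]
    r
  }, character(1))
  pool
}

.plant_fitness <- function(design, spec) {
  pool_aa <- tidyr::expand_grid(position = design$residues,
                                aa = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*"))
  if (!is.null(spec$true_relative_fitness)) {
    f <- dplyr::left_join(pool_aa, spec$true_relative_fitness,
                          by = c("position", "aa"))
    if (anyNA(f$fitness))
      stop("true_relative_fitness does not cover every (position, aa)")
    return(f)
  }
  pool_aa$fitness <- runif(nrow(pool_aa), 0, 1.2)
  wt_aa <- design$wt_aa[design$mutable_codons]
  syn <- pool_aa$aa == wt_aa[match(pool_aa$position, design$residues)]
  pool_aa$fitness[syn] <- spec$wt_fitness
  pool_aa
}

.random_hexamers <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# substitution errors at rate p, substituting to one of the 3 other bases
.apply_errors <- function(seqs, read_len, p) {
  if (p <= 0 || !length(seqs)) return(seqs)
  total <- length(seqs) * read_len
  nerr <- rbinom(1L, total, p)
  if (nerr == 0L) return(seqs)
  idx <- sample.int(total, nerr)
  read <- (idx - 1L) %/% read_len + 1L
  pos <- (idx - 1L) %% read_len + 1L
  cur <- substring(seqs[read], pos, pos)
  bases <- c("A", "C", "G", "T")
  alt <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), character(1),
                USE.NAMES = FALSE)
  .inject_errors_cpp(seqs, read, pos, alt)
}

#' Simulate a DMS sequencing experiment with planted fitness values
#'
#' Generates gzip FASTQ read pairs for every sample of a two-timepoint,
#' two-condition, replicated selection experiment, plus the sample
#' metadata and the ground truth. Library molecules carry one NNK codon at
#' one mutable position (molecules whose NNK codon equals the wild-type
#' codon are wild type); t0 frequencies are uniform over molecule classes
#' and t1 frequencies follow `f0 * 2^(g * hours)` (renormalized) with
#' `g = fitness * base_growth_rate` under selection and `base_growth_rate`
#' without. Reads are the first `read_len` bases of the insert and the
#' reverse complement of the last `read_len` (150-bp pairs overlap the
#' 258-nt insert by 42 bp); substitution errors are applied per base, and
#' Phred strings carry the quality implied by the error rate. All draws
#' derive from `spec$seed`.
#'
#' @param design An [amplicon_design()].
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return List: `metadata` (tibble; also written as `metadata.tsv`),
#'   `truth` (per molecule class: planted frequency, growth rates,
#'   relative fitness; `truth.tsv`), `truth_counts` (the multinomially
#'   drawn per-sample counts; `truth_counts.tsv`) and `dir`.
#' @export
simulate_library <- function(design, spec, dir) {
  stopifnot(inherits(design, "amplicon_design"),
            inherits(spec, "simulation_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(spec$seed, .simulate_library_impl(design, spec, dir))
}

.simulate_library_impl <- function(design, spec, dir) {
  pool <- .variant_pool(design)
  planted <- .plant_fitness(design, spec)
  pool <- dplyr::left_join(pool, planted, by = c("position", "aa"))
  pool$fitness[pool$class == "wt"] <- spec$wt_fitness
  pool$f_t0 <- 1 / nrow(pool)
  g0 <- spec$base_growth_rate
  h <- spec$culture_hours
  pool$g_spc <- pool$fitness * g0
  pool$g_nospc <- g0
  stopifnot(abs(sum(pool$f_t0) - 1) < 1e-9)

  freq_t1 <- function(g) {
    f <- pool$f_t0 * 2^(g * h)
    f / sum(f)
  }
  f1 <- list(spc = freq_t1(pool$g_spc), nospc = freq_t1(pool$g_nospc))
  cfu1 <- list(spc = spec$cfu_t0 * sum(pool$f_t0 * 2^(pool$g_spc * h)),
               nospc = spec$cfu_t0 * sum(pool$f_t0 * 2^(pool$g_nospc * h)))
  if (!is.null(spec$cfu_t1)) cfu1 <- as.list(spec$cfu_t1)

  read_len <- design$read_len
  qchar <- if (spec$per_base_error > 0) {
    rawToChar(as.raw(33L + max(2L, round(-10 * log10(spec$per_base_error)))))
  } else rawToChar(as.raw(33L + 40L))

  meta <- list(); tcounts <- list()
  for (rep_i in seq_len(spec$replicates)) {
    for (cond in c("spc", "nospc")) {
      for (tp in c("t0", "t1")) {
        sid <- sprintf("rep%d_%s_%s", rep_i, cond, tp)
        depth <- if (tp == "t0") spec$depth_t0 else spec$depth_t1
        f <- if (tp == "t0") pool$f_t0 else f1[[cond]]
        counts <- if (depth > 0) as.vector(rmultinom(1L, depth, f)) else
          integer(nrow(pool))
        fq1 <- file.path(dir, paste0(sid, "_R1.fastq.gz"))
        fq2 <- file.path(dir, paste0(sid, "_R2.fastq.gz"))
        vidx <- rep.int(seq_len(nrow(pool)), counts)
        if (length(vidx)) vidx <- sample(vidx)  # shuffle molecule order
        inserts <- if (length(vidx) == 0L) character(0) else
          paste0(.random_hexamers(length(vidx), design$hexamer_len),
                 design$anchor5, pool$reporter[vidx], design$anchor3,
                 .random_hexamers(length(vidx), design$hexamer_len))
        fwd <- substr(inserts, 1L, read_len)
        rev <- .revcomp(substr(inserts, design$insert_len - read_len + 1L,
                               design$insert_len))
        fwd <- .apply_errors(fwd, read_len, spec$per_base_error)
        rev <- .apply_errors(rev, read_len, spec$per_base_error)
        qual <- strrep(qchar, read_len)
        ids <- sprintf("%s:%d", sid, seq_along(fwd))
        write_fastq(fwd, rep(qual, length(fwd)), fq1, ids = ids)
        write_fastq(rev, rep(qual, length(rev)), fq2, ids = ids)
        meta[[sid]] <- tibble::tibble(
          sample_id = sid, replicate = rep_i, condition = cond,
          timepoint = tp,
          cfu = if (tp == "t0") spec$cfu_t0 else cfu1[[cond]],
          culture_hours = h, depth = depth,
          fastq1 = fq1, fastq2 = fq2)
        tcounts[[sid]] <- tibble::tibble(
          sample_id = sid, position = pool$position, codon = pool$codon,
          aa = pool$aa, class = pool$class, count = counts)
      }
    }
  }
  metadata <- dplyr::bind_rows(meta)
  truth <- pool[, c("position", "codon", "aa", "class", "f_t0", "fitness",
                    "g_spc", "g_nospc")]
  truth_counts <- dplyr::bind_rows(tcounts)
  readr::write_tsv(metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(truth_counts, file.path(dir, "truth_counts.tsv"))
  list(metadata = metadata, truth = truth, truth_counts = truth_counts,
       dir = dir)
}

#' Simulate a toeprint peak table from stall sites
#'
#' Peaks are placed at the fragment lengths predicted by the codon-offset
#' model; intensities are the site weights with Gaussian jitter
#' (sd `noise_sd`), floored at zero.
#'
#' @param stall_sites Data frame with columns `codon` and `weight`
#'   (weights >= 0), or an empty data frame for no signal.
#' @param calib A [toeprint_calibration()].
#' @param noise_sd Intensity jitter standard deviation.
#' @param seed Optional seed for the jitter.
#' @return Tibble with `length_nt`, `intensity`.
#' @export
simulate_toeprint_peaks <- function(stall_sites, calib, noise_sd = 0,
                                    seed = NULL) {
  stopifnot(inherits(calib, "toeprint_calibration"))
  if (NROW(stall_sites) == 0L)
    return(tibble::tibble(length_nt = integer(), intensity = numeric()))
  stopifnot(all(c("codon", "weight") %in% names(stall_sites)),
            all(stall_sites$weight >= 0))
  jitter_fn <- function() {
    pmax(0, stall_sites$weight + rnorm(NROW(stall_sites), 0, noise_sd))
  }
  intensity <- if (is.null(seed)) jitter_fn() else
    withr::with_seed(seed, jitter_fn())
  tibble::tibble(length_nt = predict_length(stall_sites$codon, calib),
                 intensity = intensity)
}
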