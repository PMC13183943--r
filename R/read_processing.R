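#' Quality-filtering policy for sequencing reads
#'
#' Mirrors the three per-read rules of common FASTQ preprocessors: a base is
#' "qualified" if its Phred score is at least `qualified_q`; a read fails if
#' more than `max_unqualified_pct` percent of its bases are unqualified, or
#' if its mean Phred score falls below `min_avg_q`. The defaults (Q20 / 30%
#' / Q25) are the settings used for the CliM DMS libraries.
#'
#' @param qualified_q Minimum Phred score for a qualified base.
#' @param max_unqualified_pct Maximum percentage of unqualified bases.
#' @param min_avg_q Minimum mean Phred score per read.
#' @return An object of class `quality_policy`.
#' @export
quality_policy <- function(qualified_q = 20L, max_unqualified_pct = 30,
                           min_avg_q = 25) {
  stopifnot(qualified_q >= 0, qualified_q <= 60,
            max_unqualified_pct >= 0, max_unqualified_pct <= 100,
            min_avg_q >= 0)
  structure(list(qualified_q = as.integer(qualified_q),
                 max_unqualified_pct = as.numeric(max_unqualified_pct),
                 min_avg_q = as.numeric(min_avg_q)),
            class = "quality_policy")
}

.phred_to_string <- function(q) {
  vapply(q, function(x) rawToChar(as.raw(x + 33L)), character(1))
}

.string_to_phred <- function(s) {
  lapply(s, function(x) as.integer(charToRaw(x)) - 33L)
}

#' Filter a read on per-base quality
#'
#' A read fails when the percentage of bases with Phred score below
#' `policy$qualified_q` exceeds `policy$max_unqualified_pct`, or when the
#' arithmetic mean Phred score is below `policy$min_avg_q`.
#'
#' @param seq Read sequence (single string).
#' @param qual Integer Phred scores, one per base.
#' @param policy A [quality_policy()].
#' @return List with `pass` (logical) and `reason` (`NA`, `"unqualified"`
#'   or `"mean_quality"`; the unqualified-fraction rule is reported first
#'   when both fail).
#' @export
quality_filter <- function(seq, qual, policy = quality_policy()) {
  stopifnot(inherits(policy, "quality_policy"))
  if (nchar(seq) != length(qual))
    stop("sequence and quality lengths differ (", nchar(seq), " vs ",
         length(qual), ")")
  if (length(qual) == 0L) stop("empty read")
  pct_unq <- 100 * mean(qual < policy$qualified_q)
  if (pct_unq > policy$max_unqualified_pct)
    return(list(pass = FALSE, reason = "unqualified"))
  if (mean(qual) < policy$min_avg_q)
    return(list(pass = FALSE, reason = "mean_quality"))
  list(pass = TRUE, reason = NA_character_)
}

#' Merge one read pair by its 3' overlap
#'
#' The mate `seq2` is supplied in sequencer orientation and is
#' reverse-complemented internally. All ungapped overlap lengths from
#' `min_overlap` up to the shorter read length are scored by the number of
#' matching bases; the best-scoring overlap wins, ties going to the longer
#' overlap. At mismatching overlap positions the base with the higher
#' quality is kept (ties keep read 1's base) and the consensus quality is
#' the higher of the two. The pair is rejected when no overlap reaches
#' `min_overlap` or the best overlap's mismatch fraction exceeds
#' `max_mismatch_frac`.
#'
#' @param seq1,qual1 Forward read and integer Phred scores.
#' @param seq2,qual2 Reverse read (sequencer orientation) and Phred scores.
#' @param min_overlap Minimum acceptable overlap (bases).
#' @param max_mismatch_frac Maximum mismatch fraction within the overlap.
#' @return On success, list with `seq`, `qual`, `overlap`. On rejection,
#'   list with `reason` (`"no_overlap"`, `"mismatch"` or `"empty"`).
#' @examples
#' m <- merge_pair("ACGTACGTACGTACGT", rep(30L, 16),
#'                 climkit:::.revcomp("ACGTACGTACGTACGT"), rep(30L, 16))
#' m$overlap  # full-length overlap: identical reads
#' @export
merge_pair <- function(seq1, qual1, seq2, qual2, min_overlap = 10L,
                       max_mismatch_frac = 0.25) {
  res <- .merge_pairs_cpp(seq1, .phred_to_string(list(qual1)),
                          seq2, .phred_to_string(list(qual2)),
                          as.integer(min_overlap), max_mismatch_frac)
  st <- res$status[1L]
  if (st == 0L)
    return(list(seq = res$seq[1L], qual = .string_to_phred(res$qual[1L])[[1L]],
                overlap = res$overlap[1L]))
  list(reason = c("no_overlap", "mismatch", "empty")[st])
}

.revcomp <- function(x) {
  suppressWarnings(
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

#' Read a FASTQ file into sequences and quality strings
#'
#' @param path FASTQ path, plain or gzipped.
#' @return List with `seq` and `qual` character vectors (Phred+33).
#' @export
read_fastq <- function(path) {
  # Biostrings warns when dropping per-record metadata columns on coercion;
  # record ids are irrelevant downstream
  suppressWarnings({
    x <- Biostrings::readQualityScaledDNAStringSet(path,
                                                   quality.scoring = "phred")
    list(seq = unname(as.character(x)),
         qual = unname(as.character(Biostrings::quality(x))))
  })
}

#' Write a FASTQ file (Phred+33), gzipped when the path ends in .gz
#'
#' @param seq,qual Character vectors of sequences and quality strings.
#' @param path Output path.
#' @param ids Optional record identifiers.
#' @export
write_fastq <- function(seq, qual, path, ids = NULL) {
  stopifnot(length(seq) == length(qual))
  if (is.null(ids)) ids <- paste0("read", seq_along(seq))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(seq))
    writeLines(paste0("@", ids, "\n", seq, "\n+\n", qual), con)
  invisible(path)
}

#' Filter and merge a file pair of 150-bp reads
#'
#' Applies [quality_filter()] to each mate (both must pass), then merges the
#' surviving pairs with the overlap consensus of [merge_pair()]. Per-sample
#' accounting (pairs in, merged, rejections by reason) is returned and can
#' be written as JSON.
#'
#' @param fq1,fq2 Paths to the mate FASTQ files.
#' @param policy A [quality_policy()].
#' @param min_overlap,max_mismatch_frac Overlap-merging parameters; see
#'   [merge_pair()].
#' @param out_fastq Optional path for the merged FASTQ.
#' @param out_report Optional path for the JSON report.
#' @return List with `seq`, `qual` (merged reads) and `report`.
#' @export
process_reads <- function(fq1, fq2, policy = quality_policy(),
                          min_overlap = 10L, max_mismatch_frac = 0.25,
                          out_fastq = NULL, out_report = NULL) {
  r1 <- read_fastq(fq1)
  r2 <- read_fastq(fq2)
  if (length(r1$seq) != length(r2$seq))
    stop("mate files differ in record count")
  n <- length(r1$seq)
  report <- list(pairs_in = n, fail_quality = 0L, merged = 0L,
                 reject_no_overlap = 0L, reject_mismatch = 0L)
  seq <- character(0); qual <- character(0)
  if (n > 0L) {
    s1 <- .phred_stats_cpp(r1$qual, policy$qualified_q)
    s2 <- .phred_stats_cpp(r2$qual, policy$qualified_q)
    ok <- 100 * s1[, 2L] <= policy$max_unqualified_pct &
      s1[, 1L] >= policy$min_avg_q &
      100 * s2[, 2L] <= policy$max_unqualified_pct &
      s2[, 1L] >= policy$min_avg_q
    report$fail_quality <- sum(!ok)
    if (any(ok)) {
      m <- .merge_pairs_cpp(r1$seq[ok], r1$qual[ok], r2$seq[ok], r2$qual[ok],
                            as.integer(min_overlap), max_mismatch_frac)
      keep <- m$status == 0L
      report$merged <- sum(keep)
      report$reject_no_overlap <- sum(m$status == 1L | m$status == 3L)
      report$reject_mismatch <- sum(m$status == 2L)
      seq <- m$seq[keep]
      qual <- m$qual[keep]
    }
  }
  if (!is.null(out_fastq)) write_fastq(seq, qual, out_fastq)
  if (!is.null(out_report))
    jsonlite::write_json(report, out_report, auto_unbox = TRUE)
  list(seq = seq, qual = qual, report = report)
}
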