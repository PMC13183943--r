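#' Parse a merged insert against the amplicon design
#'
#' A merged read is accepted only when its length equals the design's insert
#' length (any other length is presumed to contain an indel) and both 3-nt
#' anchors match exactly at their fixed coordinates (positions 7-9 and
#' 250-252 of the 258-nt CliM insert). The hexamer spacers are skipped; the
#' reporter (240 nt) is extracted for codon-level comparison.
#'
#' @param seq Merged insert sequence (single string).
#' @param design An [amplicon_design()].
#' @return List with `ok = TRUE` and `reporter`, or `ok = FALSE` and
#'   `reason` (`"indel"` or `"anchor"`).
#' @export
parse_insert <- function(seq, design) {
  stopifnot(inherits(design, "amplicon_design"))
  co <- .insert_coords(design)
  if (nchar(seq) != design$insert_len)
    return(list(ok = FALSE, reason = "indel"))
  if (substr(seq, co$anchor5[1], co$anchor5[2]) != design$anchor5 ||
      substr(seq, co$anchor3[1], co$anchor3[2]) != design$anchor3)
    return(list(ok = FALSE, reason = "anchor"))
  list(ok = TRUE, reporter = substr(seq, co$reporter[1], co$reporter[2]))
}

#' Classify a reporter sequence as wild type, single-codon variant or discard
#'
#' Codon-by-codon comparison with the wild-type reporter. Zero mismatched
#' codons is wild type; exactly one mismatched codon at a mutable position
#' is a single variant (reported with its protein residue number, observed
#' codon and amino acid, stop codons as `"*"`); more than one mismatch
#' (`"multi"`) or a single mismatch outside the mutable window (`"offsite"`)
#' is discarded. Observed codons are not required to match the NNK pattern
#' (third base G/T) — sequencing errors produce non-NNK codons — but are
#' flagged via `is_nnk` so downstream filters can drop them.
#'
#' @param reporter Reporter sequence (same length as `design$wt_reporter`).
#' @param design An [amplicon_design()].
#' @return List with `class` in `"wt"`, `"single"`, `"discard"`; for singles
#'   also `position` (protein residue), `codon`, `aa`, `is_nnk`; for
#'   discards `reason`.
#' @export
classify_reporter <- function(reporter, design) {
  stopifnot(inherits(design, "amplicon_design"))
  if (nchar(reporter) != nchar(design$wt_reporter))
    stop("reporter length mismatch")
  obs <- substring(reporter,
                   seq(1L, by = 3L, length.out = design$n_codons),
                   seq(3L, by = 3L, length.out = design$n_codons))
  mis <- which(obs != design$wt_codons)
  if (length(mis) == 0L) return(list(class = "wt"))
  if (length(mis) > 1L) return(list(class = "discard", reason = "multi"))
  slot <- match(mis, design$mutable_codons)
  if (is.na(slot)) return(list(class = "discard", reason = "offsite"))
  codon <- obs[mis]
  if (!grepl("^[ACGT]{3}$", codon))
    return(list(class = "discard", reason = "ambiguous"))
  list(class = "single", position = design$residues[slot], codon = codon,
       aa = translate_codons(codon), is_nnk = .is_nnk(codon))
}

.is_nnk <- function(codon) substr(codon, 3L, 3L) %in% c("G", "T")

#' Count variants over a stream of merged reads
#'
#' Runs [parse_insert()] and [classify_reporter()] over every merged read
#' and accumulates a per-sample count table. The bookkeeping identity
#' `wt + sum(variant counts) + sum(discards) = reads in` holds exactly.
#'
#' @param seqs Character vector of merged insert sequences.
#' @param design An [amplicon_design()].
#' @param sample_id Optional sample label stored on the table.
#' @return An object of class `variant_count_table`: list with `sample_id`,
#'   `wt_count`, `counts` (tibble: position, codon, aa, is_nnk, count),
#'   `discards` (named integer: indel/anchor/multi/offsite/ambiguous) and
#'   `reads_in`.
#' @export
count_variants <- function(seqs, design, sample_id = NA_character_) {
  stopifnot(inherits(design, "amplicon_design"))
  n <- length(seqs)
  discards <- c(indel = 0L, anchor = 0L, multi = 0L, offsite = 0L,
                ambiguous = 0L)
  wt_count <- 0L
  counts <- tibble::tibble(position = integer(), codon = character(),
                           aa = character(), is_nnk = logical(),
                           count = integer())
  if (n > 0L) {
    # collapse to unique sequences: error-free reads of the same molecule
    # class are identical, so classification cost scales with diversity
    tab <- table(seqs)
    useq <- names(tab)
    w <- as.integer(tab)
    co <- .insert_coords(design)
    len_ok <- nchar(useq) == design$insert_len
    discards["indel"] <- sum(w[!len_ok])
    useq <- useq[len_ok]; w <- w[len_ok]
    if (length(useq)) {
      anc_ok <- substr(useq, co$anchor5[1], co$anchor5[2]) == design$anchor5 &
        substr(useq, co$anchor3[1], co$anchor3[2]) == design$anchor3
      discards["anchor"] <- sum(w[!anc_ok])
      useq <- useq[anc_ok]; w <- w[anc_ok]
    }
    if (length(useq)) {
      rep_seq <- substr(useq, co$reporter[1], co$reporter[2])
      starts <- seq(1L, by = 3L, length.out = design$n_codons)
      mm <- vapply(seq_len(design$n_codons), function(i) {
        substr(rep_seq, starts[i], starts[i] + 2L) != design$wt_codons[i]
      }, logical(length(rep_seq)))
      mm <- matrix(mm, nrow = length(rep_seq))
      nmis <- rowSums(mm)
      wt_count <- sum(w[nmis == 0L])
      discards["multi"] <- sum(w[nmis > 1L])
      single <- which(nmis == 1L)
      if (length(single)) {
        codon_idx <- as.integer(mm[single, , drop = FALSE] %*%
                                  seq_len(design$n_codons))
        slot <- match(codon_idx, design$mutable_codons)
        onsite <- !is.na(slot)
        discards["offsite"] <- sum(w[single[!onsite]])
        if (any(onsite)) {
          si <- single[onsite]
          ci <- codon_idx[onsite]
          obs_codon <- substr(rep_seq[si], 3L * ci - 2L, 3L * ci)
          valid <- grepl("^[ACGT]{3}$", obs_codon)
          discards["ambiguous"] <- sum(w[si[!valid]])
          if (any(valid)) {
            df <- tibble::tibble(position = design$residues[slot[onsite]][valid],
                                 codon = obs_codon[valid],
                                 count = w[si][valid])
            counts <- dplyr::summarise(
              dplyr::group_by(df, .data$position, .data$codon),
              count = sum(.data$count), .groups = "drop")
            counts$aa <- translate_codons(counts$codon)
            counts$is_nnk <- .is_nnk(counts$codon)
            counts <- counts[order(counts$position, counts$codon),
                             c("position", "codon", "aa", "is_nnk", "count")]
          }
        }
      }
    }
  }
  structure(list(sample_id = sample_id, wt_count = wt_count, counts = counts,
                 discards = discards, reads_in = n),
            class = "variant_count_table")
}

#' @export
print.variant_count_table <- function(x, ...) {
  cat("<variant_count_table>", x$sample_id, ":", x$reads_in, "reads;",
      x$wt_count, "WT;", sum(x$counts$count), "variant reads over",
      nrow(x$counts), "codon variants;", sum(x$discards), "discarded\n")
  invisible(x)
}

#' Write a variant count table as TSV (plus optional discard summary JSON)
#'
#' @param vct A `variant_count_table`.
#' @param path Output TSV path (columns sample_id, position, codon, aa,
#'   is_nnk, count; the wild-type class appears as position NA, codon "WT").
#' @param discard_json Optional JSON path for the discard summary.
#' @export
write_count_table <- function(vct, path, discard_json = NULL) {
  stopifnot(inherits(vct, "variant_count_table"))
  out <- dplyr::bind_rows(
    tibble::tibble(position = NA_integer_, codon = "WT", aa = "WT",
                   is_nnk = NA, count = vct$wt_count),
    vct$counts)
  out <- dplyr::mutate(out, sample_id = vct$sample_id, .before = 1L)
  readr::write_tsv(out, path)
  if (!is.null(discard_json))
    jsonlite::write_json(as.list(vct$discards), discard_json, auto_unbox = TRUE)
  invisible(path)
}

#' Read count tables written by [write_count_table()]
#'
#' Accepts a TSV holding one or many samples (rows with codon `"WT"` carry
#' the wild-type count) and rebuilds one `variant_count_table` per sample.
#' Discard tallies are not round-tripped through the TSV.
#'
#' @param path TSV path.
#' @return Named list of `variant_count_table`s.
#' @export
read_count_tables <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("sample_id", "position", "codon", "aa", "count") %in%
                  names(x)))
  lapply(split(x, x$sample_id), function(s) {
    wt <- sum(s$count[s$codon == "WT"])
    v <- s[s$codon != "WT", c("position", "codon", "aa", "is_nnk", "count")]
    structure(list(sample_id = s$sample_id[1], wt_count = as.integer(wt),
                   counts = tibble::as_tibble(v),
                   discards = c(unknown = 0L),
                   reads_in = as.integer(wt + sum(v$count))),
              class = "variant_count_table")
  })
}
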