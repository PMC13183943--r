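#' @importFrom rlang .data
NULL

#' Reads-per-million normalization of a count table
#'
#' `rpm = count / total * 1e6`, where the total is the wild-type count plus
#' all variant counts (discarded reads are excluded from the denominator).
#'
#' @param vct A `variant_count_table` from [count_variants()].
#' @param by Aggregate synonymous codons per amino acid (`"aa"`, default)
#'   or keep per-codon keys (`"codon"`).
#' @return Tibble with columns `position`, `aa` (and `codon` if
#'   `by = "codon"`), `count`, `rpm`; the wild-type class appears as
#'   `position = NA`, `aa = "WT"`. RPM sums to 1e6 over all rows.
#' @export
rpm <- function(vct, by = c("aa", "codon")) {
  stopifnot(inherits(vct, "variant_count_table"))
  by <- match.arg(by)
  total <- vct$wt_count + sum(vct$counts$count)
  if (total <= 0) stop("empty count table: no counted reads")
  v <- vct$counts
  if (by == "aa") {
    v <- dplyr::summarise(dplyr::group_by(v, .data$position, .data$aa),
                          count = sum(.data$count), .groups = "drop")
  } else {
    v <- v[, c("position", "codon", "aa", "count")]
  }
  wt <- tibble::tibble(position = NA_integer_, aa = "WT",
                       count = vct$wt_count)
  if (by == "codon") wt$codon <- "WT"
  out <- dplyr::bind_rows(wt, v)
  out$rpm <- out$count / total * 1e6
  out
}

#' Per-variant growth rate from CFU and RPM changes
#'
#' `log2((cfu_t1 / cfu_t0) * (rpm_t1 / rpm_t0)) / hours`: the CFU ratio
#' converts within-sample relative abundances into absolute growth. The
#' rate is undefined (`NA`) when the variant has zero RPM at either
#' timepoint; no pseudocounts are used.
#'
#' @param rpm_t0,rpm_t1 Reads-per-million at the two timepoints (vectors).
#' @param cfu_t0,cfu_t1 Colony-forming units at the two timepoints.
#' @param hours Culture time between the timepoints.
#' @return Growth rate in log2 units per hour (`NA` where undefined).
#' @examples
#' growth_rate(500, 500, 1e7, 4e7, 2)   # 1.0
#' growth_rate(1000, 500, 1e7, 8e7, 3)  # log2(4)/3
#' @export
growth_rate <- function(rpm_t0, rpm_t1, cfu_t0, cfu_t1, hours) {
  if (any(cfu_t0 <= 0) || any(cfu_t1 <= 0)) stop("CFU values must be positive")
  if (any(hours <= 0)) stop("culture hours must be positive")
  g <- log2((cfu_t1 / cfu_t0) * (rpm_t1 / rpm_t0)) / hours
  g[rpm_t0 == 0 | rpm_t1 == 0 | is.na(rpm_t0) | is.na(rpm_t1)] <- NA_real_
  g
}

#' Relative fitness under selection
#'
#' The ratio of a variant's growth rate with antibiotic to its growth rate
#' without, paired within a replicate. Undefined (`NA`) when either rate is
#' undefined or the no-antibiotic rate is not positive (a non-growing
#' reference makes the ratio uninterpretable).
#'
#' @param g_spc Growth rate under selection (log2 units/h).
#' @param g_nospc Growth rate without selection.
#' @return Relative fitness (vectors recycle).
#' @export
relative_fitness <- function(g_spc, g_nospc) {
  r <- g_spc / g_nospc
  r[is.na(g_spc) | is.na(g_nospc) | g_nospc <= 0] <- NA_real_
  r
}

.check_metadata <- function(metadata) {
  need <- c("sample_id", "replicate", "condition", "timepoint", "cfu",
            "culture_hours")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (!all(metadata$condition %in% c("spc", "nospc")))
    stop('condition must be "spc" or "nospc"')
  if (!all(metadata$timepoint %in% c("t0", "t1")))
    stop('timepoint must be "t0" or "t1"')
  invisible(metadata)
}

#' Per-variant fitness from count tables and sample metadata
#'
#' For every replicate, computes per-variant growth rates in each condition
#' from the t0/t1 count tables (RPM change scaled by the CFU ratio), then
#' the relative fitness as their within-replicate ratio. Variants are keyed
#' by (position, amino acid) with synonymous codon counts summed before
#' normalization (`by = "codon"` keeps codon resolution). Read support is
#' recorded as the t0 count in each condition; a variant passes the read
#' filter in a replicate only if both t0 counts reach `min_reads`.
#'
#' @param tables Named list of `variant_count_table`s, names = sample ids.
#' @param metadata Tibble with columns sample_id, replicate, condition
#'   (`"spc"`/`"nospc"`), timepoint (`"t0"`/`"t1"`), cfu, culture_hours.
#' @param min_reads Read-support threshold (default 8).
#' @param by `"aa"` (default) or `"codon"`.
#' @return Tibble with one row per replicate x variant: growth rates,
#'   relative fitness, t0 read support and `pass_filter`.
#' @export
dms_fitness <- function(tables, metadata, min_reads = 8L,
                        by = c("aa", "codon")) {
  by <- match.arg(by)
  .check_metadata(metadata)
  if (!all(metadata$sample_id %in% names(tables)))
    stop("metadata sample_id missing from tables")
  key <- if (by == "codon") c("position", "codon", "aa") else c("position", "aa")
  per_sample <- lapply(seq_len(nrow(metadata)), function(i) {
    m <- metadata[i, ]
    x <- rpm(tables[[m$sample_id]], by = by)
    x$replicate <- m$replicate
    x$condition <- m$condition
    x$timepoint <- m$timepoint
    x$cfu <- m$cfu
    x$hours <- m$culture_hours
    x
  })
  long <- dplyr::bind_rows(per_sample)
  wide <- tidyr::pivot_wider(long,
                             id_cols = dplyr::all_of(c("replicate", "condition", key)),
                             names_from = "timepoint",
                             values_from = c("count", "rpm", "cfu", "hours"),
                             values_fill = list(count = 0L, rpm = 0))
  # a variant absent from one timepoint has rpm 0 there, but the sample's
  # CFU/hours still apply; recover them per (replicate, condition)
  meta_rc <- tidyr::pivot_wider(metadata,
                                id_cols = dplyr::all_of(c("replicate", "condition")),
                                names_from = "timepoint", values_from = "cfu",
                                names_prefix = "cfu_")
  hours_rc <- dplyr::distinct(metadata, .data$replicate, .data$condition,
                              hours = .data$culture_hours)
  wide <- dplyr::select(wide, -dplyr::any_of(c("cfu_t0", "cfu_t1",
                                               "hours_t0", "hours_t1")))
  wide <- dplyr::left_join(wide, meta_rc, by = c("replicate", "condition"))
  wide <- dplyr::left_join(wide, hours_rc, by = c("replicate", "condition"))
  wide$growth_rate <- growth_rate(wide$rpm_t0, wide$rpm_t1,
                                  wide$cfu_t0, wide$cfu_t1, wide$hours)
  res <- tidyr::pivot_wider(wide,
                            id_cols = dplyr::all_of(c("replicate", key)),
                            names_from = "condition",
                            values_from = c("growth_rate", "count_t0", "count_t1"))
  res$relative_fitness <- relative_fitness(res$growth_rate_spc,
                                           res$growth_rate_nospc)
  res$pass_filter <- !is.na(res$count_t0_spc) & !is.na(res$count_t0_nospc) &
    res$count_t0_spc >= min_reads & res$count_t0_nospc >= min_reads
  res
}

#' Aggregate replicate fitness values into per-variant means
#'
#' The mean of the within-replicate relative-fitness values is reported per
#' variant. A variant failing the read filter in any contributing sample,
#' or with an undefined fitness in any replicate, is masked (`NA`), not
#' zeroed.
#'
#' @param records Output of [dms_fitness()].
#' @return Tibble keyed by variant with `n_replicates`, `mean_fitness`
#'   (masked to `NA` when not all replicates pass) and `all_pass`.
#' @export
aggregate_fitness <- function(records) {
  key <- intersect(c("position", "codon", "aa"), names(records))
  out <- dplyr::summarise(
    dplyr::group_by(records, dplyr::across(dplyr::all_of(key))),
    n_replicates = dplyr::n(),
    all_pass = all(.data$pass_filter & !is.na(.data$relative_fitness)),
    mean_fitness = mean(.data$relative_fitness),
    .groups = "drop")
  out$mean_fitness[!out$all_pass] <- NA_real_
  out
}

#' Position x amino-acid fitness heatmap matrix
#'
#' @param agg Output of [aggregate_fitness()] (aa-level).
#' @param design An [amplicon_design()]; defines the position axis.
#' @param aa_order Row order; default the 20 amino acids plus stop (`"*"`).
#' @return Numeric matrix (substituted residue x protein position); masked
#'   or unobserved variants are `NA`.
#' @export
heatmap_matrix <- function(agg, design,
                           aa_order = c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*")) {
  stopifnot(inherits(design, "amplicon_design"))
  positions <- design$residues
  m <- matrix(NA_real_, nrow = length(aa_order), ncol = length(positions),
              dimnames = list(aa_order, positions))
  v <- agg[!is.na(agg$position) & agg$aa %in% aa_order, ]
  m[cbind(match(v$aa, aa_order), match(v$position, positions))] <- v$mean_fitness
  m
}

#' Write fitness results: long TSV plus wide heatmap TSV
#'
#' @param records Per-replicate records from [dms_fitness()].
#' @param agg Aggregated values from [aggregate_fitness()].
#' @param design The [amplicon_design()].
#' @param long_path,heatmap_path Output TSV paths.
#' @export
write_fitness <- function(records, agg, design, long_path, heatmap_path) {
  readr::write_tsv(records, long_path)
  m <- heatmap_matrix(agg, design)
  wide <- tibble::as_tibble(m, rownames = "aa")
  readr::write_tsv(wide, heatmap_path)
  invisible(list(long = long_path, heatmap = heatmap_path))
}
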