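#' @useDynLib climkit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom rmultinom quantile cor sd setNames
#' @importFrom utils head tail
NULL

# Published amplicon for the Cd CliM deep mutational scanning library.
# Insert anatomy (1-based coordinates on the 258-nt insert):
#   1-6     randomized hexamer ("NNNNNN")
#   7-9     bc5 anchor, TAG
#   10-249  240-nt reporter (80 codons)
#   250-252 bc7 anchor, GGT
#   253-258 randomized hexamer
# Reporter codons 1-32 are the GFP C-terminus/linker, codons 33-72 carry
# CliM residues 38-77 (the saturation-mutagenesis window; residue 77 is an
# engineered Lys replacing the native stop), codons 73-80 the FLAG tag.
CD_CLIM_ADAPTER5 <- "AATGATACGGCGACCACCGAGATCTACACAGCGCTAGACACTCTTTCCCTACACGACGCTCTTCCGATCT"
CD_CLIM_ADAPTER3 <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCACCCGCGGTTATCTCGTATGCCGTCTTCTGCTTG"
CD_CLIM_REPORTER <- paste0(
  "AGAGACCACATGGTCCTTCTTGAGTTTGTAACAGCTGCTGGGATTACACATGGCATGGATGAACTATAC",
  "AAAAAAGACCTCTTAAATCATAAAATTAAGTATGTTTTAATAAGAGACATATTTGTAAATAGAATTACA",
  "TATTCTGAAGAACGACTGCCTAAACAGTATATAGTTTTTCAGAAATATGATATTTGGCGGTATTGTAGT",
  "TTATTTAAAGACTATAAAGACGACGACGACAAA")

.valid_dna <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl("^[ACGT]+$", x)
}

#' Construct an amplicon design
#'
#' Describes the fixed architecture of a saturation-mutagenesis sequencing
#' library: flanking Illumina adapters, two randomized hexamer spacers, two
#' 3-nt anchors (`bc5`/`bc7`), and the reporter carrying the mutable codon
#' window. The default values in [cd_clim_design()] reproduce the Cd CliM
#' library, whose 258-nt insert is read as 150-bp pairs overlapping by 42 bp.
#'
#' @param adapter5,adapter3 Flanking adapter sequences (not part of the
#'   insert; retained for provenance).
#' @param wt_reporter Wild-type reporter sequence; length must be a multiple
#'   of 3 (240 nt for the CliM design).
#' @param mutable_codons Integer vector of reporter codon indices subject to
#'   NNK mutagenesis, in order.
#' @param residues Integer vector of protein residue numbers, one per
#'   mutable codon (38-77 for CliM).
#' @param anchor5,anchor3 3-nt anchors delimiting the reporter.
#' @param hexamer_len Length of each randomized spacer.
#' @param read_len Sequencing read length (bp).
#' @return An object of class `amplicon_design`.
#' @export
amplicon_design <- function(adapter5, adapter3, wt_reporter, mutable_codons,
                            residues, anchor5 = "TAG", anchor3 = "GGT",
                            hexamer_len = 6L, read_len = 150L) {
  stopifnot(.valid_dna(adapter5), .valid_dna(adapter3), .valid_dna(wt_reporter),
            .valid_dna(anchor5), .valid_dna(anchor3))
  if (nchar(wt_reporter) %% 3L != 0L)
    stop("wt_reporter length must be a multiple of 3")
  n_codons <- nchar(wt_reporter) %/% 3L
  mutable_codons <- as.integer(mutable_codons)
  residues <- as.integer(residues)
  if (length(mutable_codons) != length(residues))
    stop("mutable_codons and residues must pair 1:1")
  if (any(mutable_codons < 1L | mutable_codons > n_codons))
    stop("mutable codon index outside reporter")
  design <- structure(list(
    adapter5 = adapter5, adapter3 = adapter3,
    anchor5 = anchor5, anchor3 = anchor3,
    hexamer_len = as.integer(hexamer_len),
    wt_reporter = wt_reporter,
    mutable_codons = mutable_codons,
    residues = residues,
    read_len = as.integer(read_len)
  ), class = "amplicon_design")
  design$insert_len <- 2L * design$hexamer_len + nchar(anchor5) +
    nchar(anchor3) + nchar(wt_reporter)
  design$n_codons <- n_codons
  design$wt_codons <- substring(wt_reporter,
                                seq(1L, by = 3L, length.out = n_codons),
                                seq(3L, by = 3L, length.out = n_codons))
  design$wt_aa <- translate_codons(design$wt_codons)
  design
}

#' @export
print.amplicon_design <- function(x, ...) {
  cat("<amplicon_design> insert", x$insert_len, "nt; reporter",
      nchar(x$wt_reporter), "nt (", x$n_codons, "codons );",
      length(x$mutable_codons), "mutable codons -> residues",
      min(x$residues), "-", max(x$residues), "\n")
  invisible(x)
}

#' The Cd CliM deep-mutational-scanning amplicon design
#'
#' The published library architecture: a 258-nt insert consisting of a
#' randomized hexamer, the TAG anchor (bc5), a 240-nt reporter, the GGT
#' anchor (bc7) and a second hexamer, flanked by Illumina adapters.
#' Reporter codons 33-72 carry CliM residues 38-77 (NNK-mutagenized).
#'
#' @return An `amplicon_design`.
#' @examples
#' d <- cd_clim_design()
#' d$insert_len            # 258
#' 2 * d$read_len - d$insert_len  # pairs overlap by 42 bp
#' @export
cd_clim_design <- function() {
  amplicon_design(
    adapter5 = CD_CLIM_ADAPTER5,
    adapter3 = CD_CLIM_ADAPTER3,
    wt_reporter = CD_CLIM_REPORTER,
    mutable_codons = 33:72,
    residues = 38:77
  )
}

#' Translate codons with the standard genetic code
#'
#' @param codons Character vector of 3-nt codons.
#' @return One-letter amino acids; stops are `"*"`.
#' @export
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  if (anyNA(aa)) stop("invalid codon(s): ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  aa
}

#' Build the reference insert from a design and a pair of hexamers
#'
#' Concatenates `hexamer5 + anchor5 + wt_reporter + anchor3 + hexamer3`,
#' the molecule that sequencing reads are drawn from (adapters excluded).
#'
#' @param design An [amplicon_design()].
#' @param hexamers Character vector of two spacer sequences, each of length
#'   `design$hexamer_len` over A/C/G/T.
#' @return The insert sequence (258 nt for the CliM design).
#' @examples
#' insert <- build_reference_amplicon(cd_clim_design(), c("AAAAAA", "TTTTTT"))
#' nchar(insert)  # 258
#' @export
build_reference_amplicon <- function(design, hexamers) {
  stopifnot(inherits(design, "amplicon_design"))
  if (length(hexamers) != 2L)
    stop("hexamers must be a pair of sequences")
  for (h in hexamers) {
    if (!.valid_dna(h))
      stop("hexamers must contain only A/C/G/T")
    if (nchar(h) != design$hexamer_len)
      stop("hexamer length must be ", design$hexamer_len, ", got ", nchar(h))
  }
  paste0(hexamers[[1L]], design$anchor5, design$wt_reporter,
         design$anchor3, hexamers[[2L]])
}

# Insert coordinates of the reporter and anchors (1-based).
.insert_coords <- function(design) {
  h <- design$hexamer_len
  a5 <- nchar(design$anchor5)
  rep_start <- h + a5 + 1L
  rep_end <- rep_start + nchar(design$wt_reporter) - 1L
  list(anchor5 = c(h + 1L, h + a5),
       reporter = c(rep_start, rep_end),
       anchor3 = c(rep_end + 1L, rep_end + nchar(design$anchor3)))
}
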