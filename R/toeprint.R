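#' Toeprint calibration: one anchor pair fixes the codon-offset model
#'
#' In a toeprinting assay a stalled ribosome blocks reverse transcription,
#' so the cDNA fragment length reports the ribosome's position. Fragment
#' length decreases by one codon (3 nt) for every codon the P-site
#' advances; absolute lengths are construct- and primer-specific, so the
#' model is anchored by a single observed pair. For the Cd CliM reporter,
#' 0-site stalling with Phe76 in the P-site gives a 176-nt fragment.
#'
#' @param anchor_codon P-site codon number of the anchor signal.
#' @param anchor_length Observed fragment length (nt) for the anchor.
#' @param nt_per_codon Offset per codon (default 3).
#' @return An object of class `toeprint_calibration`.
#' @examples
#' cal <- toeprint_calibration(76, 176)
#' predict_length(75, cal)  # 179 nt (-1 site)
#' predict_length(77, cal)  # 173 nt (+1 site)
#' @export
toeprint_calibration <- function(anchor_codon, anchor_length,
                                 nt_per_codon = 3L) {
  stopifnot(anchor_codon >= 1, anchor_length > 0, nt_per_codon >= 1)
  structure(list(anchor_codon = as.integer(anchor_codon),
                 anchor_length = as.integer(anchor_length),
                 nt_per_codon = as.integer(nt_per_codon)),
            class = "toeprint_calibration")
}

#' Predict the toeprint fragment length for a P-site codon
#'
#' `anchor_length - nt_per_codon * (p_site_codon - anchor_codon)`:
#' downstream stall sites give shorter fragments.
#'
#' @param p_site_codon Codon number(s) in the P-site (>= 1).
#' @param calib A [toeprint_calibration()].
#' @return Predicted fragment length(s) in nt.
#' @export
predict_length <- function(p_site_codon, calib) {
  stopifnot(inherits(calib, "toeprint_calibration"))
  if (any(p_site_codon < 1)) stop("P-site codon must be >= 1")
  len <- calib$anchor_length -
    calib$nt_per_codon * (as.integer(p_site_codon) - calib$anchor_codon)
  if (any(len <= 0))
    stop("predicted fragment length is non-positive; codon outside model range")
  len
}

#' Assign observed toeprint peaks to stall-site codons
#'
#' Each peak is matched to the candidate codon whose predicted fragment
#' length lies within `tolerance_nt` (capillary sizing jitter; default
#' 1 nt); ties go to the smaller codon number. Peaks with no candidate
#' within tolerance are left unassigned.
#'
#' @param peaks Data frame with columns `length_nt` and `intensity` (a bare
#'   numeric vector of lengths is also accepted).
#' @param calib A [toeprint_calibration()].
#' @param candidate_codons Integer vector of candidate P-site codons.
#' @param tolerance_nt Maximum |observed - predicted| in nt.
#' @return Tibble: length_nt, intensity, codon (NA when unassigned),
#'   predicted_nt, offset_nt.
#' @export
assign_peaks <- function(peaks, calib, candidate_codons, tolerance_nt = 1L) {
  stopifnot(inherits(calib, "toeprint_calibration"))
  if (is.numeric(peaks)) peaks <- tibble::tibble(length_nt = peaks,
                                                 intensity = NA_real_)
  stopifnot(all(c("length_nt", "intensity") %in% names(peaks)))
  candidate_codons <- sort(as.integer(candidate_codons))
  pred <- predict_length(candidate_codons, calib)
  pick <- function(len) {
    d <- abs(pred - len)
    ok <- which(d <= tolerance_nt)
    if (!length(ok)) return(c(NA_integer_, NA_integer_))
    # nearest prediction; ties toward the smaller codon number
    best <- ok[order(d[ok], candidate_codons[ok])][1L]
    c(candidate_codons[best], pred[best])
  }
  hits <- t(vapply(peaks$length_nt, pick, integer(2)))
  tibble::tibble(length_nt = peaks$length_nt, intensity = peaks$intensity,
                 codon = hits[, 1L], predicted_nt = hits[, 2L],
                 offset_nt = peaks$length_nt - hits[, 2L])
}

#' Read a toeprint peak table from CSV
#'
#' @param path CSV with columns `length_nt`, `intensity`.
#' @return Tibble.
#' @export
read_peaks <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("length_nt", "intensity") %in% names(x)))
  x
}
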