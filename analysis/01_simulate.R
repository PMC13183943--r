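#!/usr/bin/env Rscript
# Generate the synthetic datasets for the downstream analyses:
#  - a DMS selection experiment (2 replicates, +/-Spc, t0/t1) with planted
#    relative-fitness values over CliM residues 38-77,
#  - a toeprint peak table for a 0-site/-1-site stalling mixture.
# Reads land under scratch/analysis/dms (bulky), tables under results/.

suppressPackageStartupMessages(library(climkit))

dir.create("results", showWarnings = FALSE)
design <- cd_clim_design()
print(design)

spec <- simulation_spec(depth_t0 = 5e4, depth_t1 = 5e4,
                        per_base_error = 0.001, replicates = 2L,
                        seed = 20260919L)
sim <- simulate_library(design, spec, "scratch/analysis/dms")
cat(sprintf("simulated %d samples (%d molecule classes, %d read pairs each)\n",
            nrow(sim$metadata), nrow(sim$truth), spec$depth_t0))
cat("planted relative fitness: wild type 0.2, variants uniform on [0, 1.2]\n")
cat("metadata:", file.path(sim$dir, "metadata.tsv"), "\n")

calib <- toeprint_calibration(anchor_codon = 76, anchor_length = 176)
peaks <- simulate_toeprint_peaks(
  data.frame(codon = c(75, 76), weight = c(0.25, 1.0)),
  calib, noise_sd = 0.05, seed = 20260919L)
readr::write_csv(peaks, "results/toeprint_peaks.csv")
cat("toeprint peaks (nt):", peaks$length_nt,
    "-> results/toeprint_peaks.csv\n")
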