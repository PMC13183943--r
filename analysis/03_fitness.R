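#!/usr/bin/env Rscript
# Growth rates, relative fitness and the position x amino-acid heatmap,
# with recovery of the planted values as the internal control.

suppressPackageStartupMessages(library(climkit))

design <- cd_clim_design()
md <- readr::read_tsv("scratch/analysis/dms/metadata.tsv",
                      show_col_types = FALSE)
truth <- readr::read_tsv("scratch/analysis/dms/truth.tsv",
                         show_col_types = FALSE)
tabs <- read_count_tables("results/counts.tsv")

rec <- dms_fitness(tabs, md, min_reads = 8L)
agg <- aggregate_fitness(rec)
write_fitness(rec, agg, design,
              "results/fitness_long.tsv", "results/fitness_heatmap.tsv")

truth_aa <- unique(truth[truth$class == "single",
                         c("position", "aa", "fitness")])
j <- merge(agg[!is.na(agg$mean_fitness), ], truth_aa,
           by = c("position", "aa"))
rho <- cor(j$mean_fitness, j$fitness, method = "spearman")
cat(sprintf("variants scored: %d; passing the 8-read filter in all samples: %d\n",
            nrow(agg), sum(agg$all_pass)))
cat(sprintf("Spearman(planted, estimated relative fitness) = %.3f over %d variants\n",
            rho, nrow(j)))
cat("wrote results/fitness_long.tsv and results/fitness_heatmap.tsv\n")
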