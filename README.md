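# climkit

Quantitative toolkit for studying the CliM ribosome-arrest peptide of
*Clostridioides difficile* — and, more generally, for the three kinds of
measurement that anchor arrest-peptide work:

1. **Deep mutational scanning (DMS).** An NNK saturation-mutagenesis
   library over CliM residues 38–77 is selected with and without
   spectinomycin; loss of arrest permits readthrough into a resistance
   gene, so each variant's abundance trajectory reports its arrest
   activity. From raw 150-bp paired-end FASTQ files the package merges
   pairs (the 258-nt insert gives a 42-bp overlap), applies the
   Q20 / 30% / Q25 quality rules, counts single-codon variants, and scores

   growth rate = log2[(CFU_t1/CFU_t0) × (RPM_t1/RPM_t0)] / culture hours,
   relative fitness = g(+Spc) / g(−Spc),

   averaged over replicates with an ≥8-read support filter, into a
   position × amino-acid heatmap.
2. **Toeprinting.** A stalled ribosome blocks reverse transcription, so
   cDNA fragment length locates the P-site codon. A linear 3-nt-per-codon
   model anchored at one calibration pair (codon 76 → 176 nt for the Cd
   CliM reporter) predicts fragment lengths and assigns observed peaks to
   stall sites.
3. **Steric / conformational analysis.** Monte-Carlo van-der-Waals
   overlap volumes between union-of-spheres bodies (e.g. nascent chain vs
   release factor), in-silico sidechain truncation (Leu→Ala/Gly),
   (i, i+4) backbone hydrogen-bond censuses, extended-chain arithmetic,
   Kabsch superposition, and single-mode PLS functional-mode analysis of
   conformational ensembles.

A synthetic-data module generates DMS libraries with planted fitness
values, toeprint peak tables and ideal-helix coordinate sets, so every
stage is testable end to end without downloads.

## Worked example

The `analysis/` directory holds the numbered workflow. Running

```sh
Rscript analysis/01_simulate.R   # synthetic DMS experiment + toeprint peaks
Rscript analysis/02_count.R      # merge, filter, count per sample
Rscript analysis/03_fitness.R    # growth rates, fitness, heatmap
Rscript analysis/04_toeprint.R   # fragment-length predictions/assignments
Rscript analysis/05_steric.R     # overlap volumes, H-bond census, FMA
```

prints, among other things:

```
rep1_spc_t0: 50000 pairs -> 50000 merged -> 741 WT + 38702 variant reads, 10557 discarded
Spearman(planted, estimated relative fitness) = 0.963 over 823 variants
predicted fragment lengths for P-site codons 75/76/77: 179 176 173 nt
27 residues, extended at 3.5 A/residue: 94.5 A
18-residue ideal helix: 14 (i, i+4) O...N pairs <= 3.5 A (mean 3.09 A)
two-sphere lens: MC 1.3080 +/- 0.0019 A^3 vs exact 1.3090 A^3
overlap with probe, LEU9: 20.064 A^3 ... GLY9: 0.000 A^3
functional mode at SNR 3: cosine to truth 0.989, validation r 0.940
```

Reading these: the counting pipeline conserves every read (WT + variants +
discards = merged); planted and estimated fitness agree to Spearman 0.96
at 5×10⁴ pairs/sample (the ~21% discard rate is exactly the fraction of
reads carrying ≥1 sequencing error over 258 nt at 0.1%); the toeprint
model reproduces the −1/0/+1-site signature (179/176/173 nt); the
Monte-Carlo volume matches the closed-form two-sphere lens within its
standard error; and truncating a bulky sidechain abolishes the steric
overlap with a release-factor-like probe, the property that underlies the
Leu75 stalling mechanism. Tables land under `results/`.

The same operations are available interactively:

```r
library(climkit)
design <- cd_clim_design()
calib  <- toeprint_calibration(anchor_codon = 76, anchor_length = 176)
predict_length(75:77, calib)
#> [1] 179 176 173
```

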