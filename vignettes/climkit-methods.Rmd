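---
title: "Methods: quantifying arrest-peptide function from sequencing, toeprints and structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying arrest-peptide function from sequencing, toeprints and structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climkit)
```

climkit bundles the quantitative methods used to dissect the CliM
ribosome-arrest peptide of *Clostridioides difficile*: a deep mutational
scanning (DMS) pipeline from raw paired-end reads to a relative-fitness
heatmap, a codon-offset model for toeprinting assays, and a small geometry
engine for steric and conformational analysis of the nascent chain. This
vignette explains each model, its assumptions and tunable parameters, the
synthetic data the package generates to exercise them, and the numerical
choices made along the way.

## The amplicon and its coordinate system

The DMS library is a fixed 258-nt insert: a randomized hexamer spacer, the
anchor `TAG`, a 240-nt reporter, the anchor `GGT`, and a second hexamer,
flanked by Illumina adapters. The reporter's 80 codons comprise 24 codons
of GFP C-terminus/linker, 48 codons carrying CliM residues 30–77 (the
native stop replaced by an engineered Lys77), and an 8-codon FLAG tag.
Saturation (NNK) mutagenesis covers reporter codons 33–72, i.e. protein
residues 38–77. Sequencing is 150-bp paired-end, so the two mates overlap
the insert by `2*150 - 258 = 42` bp and a merged pair determines every
insert base.

```{r}
design <- cd_clim_design()
design
nchar(build_reference_amplicon(design, c("AAAAAA", "TTTTTT")))
```

The hexamers are treated purely as spacers that the parser skips: they are
randomized per molecule, are never used as unique molecular identifiers,
and no read deduplication is performed anywhere in the pipeline.

## Read processing

`merge_pair()` merges a pair by its best ungapped 3′ overlap. All overlap
lengths from `min_overlap` (default 10) up to the read length are scored
by matching bases; only overlaps whose mismatch fraction stays within
`max_mismatch_frac` (default 0.25) compete, and ties go to the longer
overlap. Restricting the competition to mismatch-qualifying overlaps
matters: an unconstrained "most matching bases" rule lets a long spurious
overlap (~25% of bases match by chance) outscore a shorter perfect one.
At disagreeing overlap positions the higher-quality base wins (ties keep
read 1) and the consensus quality is the higher of the two.

`quality_filter()` applies three per-read rules, with the defaults used
for the CliM libraries: a base is qualified at Phred ≥ 20; a read fails if
more than 30% of bases are unqualified or its mean Phred score is below
25. Both mates must pass before merging; the mean is an arithmetic mean of
Phred scores, not of error probabilities, because that is how the
thresholds are defined. No adapter trimming is performed — for this fixed
258-nt design the reads never run into adapter.

## Variant calling

`parse_insert()` accepts a merged read only if it is exactly 258 nt (any
other length is presumed to contain an indel — there is no gapped
alignment, a stated non-goal) and both anchors match exactly at positions
7–9 and 250–252. `classify_reporter()` then compares the 80 reporter
codons to the wild type: zero mismatches is wild type; exactly one
mismatched codon at a mutable position is a single variant, translated
with the standard genetic code (stops as `*`); anything else is discarded
(`multi`, `offsite`). Observed codons are not forced to match the NNK
pattern, since sequencing errors create non-NNK codons; they are counted
but flagged so downstream filters can drop them. The bookkeeping identity
`WT + variants + discards = reads parsed` holds exactly and is tested.

Synonymous codons at a mutable position count as variants of that codon;
aggregation to amino-acid level happens downstream (by default before RPM
normalization, configurable to per-codon via `by = "codon"`), because the
fitness heatmap is per amino acid while the library is per codon.

## Fitness model

For each variant \(v\) in a sample pair \((t_0, t_1)\):

\[
\text{growth rate}(v) = \frac{\log_2\!\left[\frac{\mathrm{CFU}_{t1}}{\mathrm{CFU}_{t0}}
\cdot \frac{\mathrm{RPM}_{t1}(v)}{\mathrm{RPM}_{t0}(v)}\right]}{\text{culture hours}},
\qquad
\text{relative fitness}(v) = \frac{g_{+\mathrm{Spc}}(v)}{g_{-\mathrm{Spc}}(v)}
\]

RPM (reads per million) is computed over wild type plus all counted
variants — discards are excluded, and no stated exclusion applies to the
wild type — and sums to \(10^6\) per sample by construction. The CFU
ratio converts within-sample relative abundance into absolute growth. No
pseudocounts are used: a zero RPM at either timepoint leaves the rate
undefined, and a non-positive −Spc rate leaves the ratio undefined rather
than sign-flipped, because a non-growing reference makes the ratio
uninterpretable.

Relative fitness is computed within each replicate and the replicate
values are averaged. The ≥8-read support filter is applied to the t0
count of each condition within each replicate (the most conservative of
the readings compatible with "at least eight reads"; the threshold and
`by` aggregation are arguments, so other choices are one keyword away).
Variants failing the filter in any contributing sample are masked (`NA`)
in the heatmap, never zeroed.

## The synthetic DMS generator

`simulate_library()` emulates the selection experiment so that the whole
pipeline is testable without downloads. Its model and defaults:

* one NNK codon per molecule, uniform over the 40 positions × 32 NNK
  codons (1280 classes); a molecule whose NNK codon equals the wild-type
  codon *is* wild type;
* planted relative fitness per (position, amino acid): wild type 0.2
  (stable arrest means poor growth under spectinomycin), variants uniform
  on \[0, 1.2\]; substitutions reproducing the wild-type amino acid
  inherit the wild-type value, since a synonymous change cannot alter the
  phenotype;
* growth: \(g_{-\mathrm{Spc}} = 1.0\,\log_2/h\) for everyone (one
  doubling per hour), \(g_{+\mathrm{Spc}} = r \cdot g_{-\mathrm{Spc}}\) —
  the direct inverse of the relative-fitness definition; t1 frequencies
  are \(f_0 2^{gh}\) renormalized over 3 culture hours, and read counts
  are multinomial at the requested depth;
* reads: the first and last 150 nt of each insert (42-bp overlap),
  per-base substitution errors at 0.1% by default, Phred+33 qualities set
  to the quality implied by the error rate (errors are uncorrelated with
  the reported quality — the simplest model, chosen deliberately);
* CFU values consistent with the planted growth
  (\(\mathrm{CFU}_{t1} = \mathrm{CFU}_{t0} \sum_v f_v 2^{g_v h}\)),
  overridable so that fitness-recovery tests can isolate the counting
  pipeline;
* everything derives from one integer seed; identical inputs give
  byte-identical FASTQ output.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: PCR jackpots and chimeras, index hopping,
plating (CFU) noise, quality-correlated and indel errors, and
position-dependent error rates. The recovery benchmarks (Spearman ≥ 0.9
between planted and estimated fitness at 2×10⁵ pairs/sample, 0.1% error,
two replicates) certify the pipeline's arithmetic, not the biology of any
particular library. Sequencing depth per sample is a free parameter (the
study's own depths are not printed); the defaults use 2×10⁵ pairs per
sample, and the bundled analysis scripts use 5×10⁴ to keep a full run in
seconds while leaving every variant comfortably above the read filter.

## Toeprint model

A stalled ribosome blocks reverse transcription at a fixed distance from
the P-site codon, so fragment length falls linearly — 3 nt per codon — as
the stall site advances. Absolute lengths depend on construct and primer,
so `toeprint_calibration()` anchors the model with one observed pair; for
the Cd CliM reporter, 0-site stalling (Phe76 in the P-site) at 176 nt.
The −1-site and +1-site predictions are then 179 and 173 nt.
`assign_peaks()` inverts the model with a default tolerance of 1 nt
(capillary sizing jitter), breaking ties toward the smaller codon. A
known edge case: the Ck CliM doublet at 152/154 nt (codons 75/74) is
spaced 2 nt, which no 3-nt model fits; the assignment table carries a
`offset_nt` column so such residuals surface instead of being absorbed.

## Steric engine

**Overlap volume.** `mc_overlap_volume()` estimates the intersection
volume of two union-of-spheres bodies (atoms with van-der-Waals radii,
Bondi values by default, overridable per element since the radius set
used originally is not stated). Uniform points are drawn over the
*intersection* of the two sphere-padded bounding boxes — this region
contains every intersection point, is never larger than either single
padded box, and makes the estimator exactly symmetric in its arguments
under a shared seed. The estimate is region volume × hit fraction with a
binomial standard error; the default 10⁶ samples put the standard error
near 0.2% of the box volume, and the two-sphere closed form
(`sphere_lens_volume()`) is the test oracle. An explicit seed is
required, so every reported volume is reproducible.

**Truncation.** `mutate_sidechain()` implements in-silico Leu→Ala/Gly
style mutations by deleting sidechain atoms (Ala keeps CB). Because atoms
are only removed, any overlap volume is non-increasing — a property the
tests exercise against a probe sphere placed where the sidechain points.

**Hydrogen-bond census.** `count_i4_hbonds()` counts (i, i+4) pairs with
O(i)···N(i+4) ≤ 3.5 Å. No explicit hydrogens are used: the criterion is
the permissive "could form" geometric reading, and the cutoff is an
argument. An ideal 18-residue helix yields exactly 14 pairs at ~3.1 Å.

**Superposition.** `superpose()` is the SVD/Kabsch least-squares rigid
fit with reflection correction; the caller supplies the paired atom
selection (e.g. phosphate backbone atoms around the peptidyl transferase
center when aligning ribosome structures) — there is no automatic chain
mapping. RMSD is invariant to any pre-transform of the mobile set, and
the implementation is cross-checked against bio3d in the tests.

**Helix fixture.** `make_helix_coords()` builds backbone atoms from
standard bond lengths/angles at ideal helical dihedrals (φ = −57°,
ψ = −47°, ω = 180°) by sequential internal-coordinate placement, giving
the canonical ~1.5 Å rise and ~100° twist per residue. It is a fixture
generator: real structures come in through `read_atoms()` (PDB/mmCIF via
bio3d).

## Functional-mode analysis

`functional_mode()` finds the single partial-least-squares latent mode:
the unit-norm linear combination \(w \propto X_c^\top y_c\) of
mean-centered coordinates maximizing covariance with a scalar observable
(for the arrest-peptide problem, backbone coordinates of the C-terminal
residues against the per-frame overlap volume with the release factor).
The model is fitted on training conformations only — for MD ensembles,
half of the replicas — and reports Pearson correlations of the projection
with the observable on both splits. Only one mode is extracted, no
deflation and no response-side scaling; with that convention the weights
coincide with the first X-loading of a standard PLS fit, which the test
suite verifies against mixOmics.

Two exactness caveats shape the fixtures: a "validation correlation of
1.0" is only attainable when the ensemble's motion is rank-1 along the
planted mode (with full-rank coordinate noise, finite-sample covariance
bends the single mode away from the planted axis), so
`simulate_mode_ensemble()` generates exactly such ensembles, with an
adjustable signal-to-noise ratio for the noisy benchmarks (cosine ≥ 0.9
at SNR 3). For a null observable, significance is judged against a
permutation null rather than a fixed threshold.

## Problem sizes and numerical notes

The test suite runs the full pipeline at the benchmark conditions
(2×10⁵ pairs/sample × 8 samples, 0.1% error) in a few minutes; the
analysis scripts use 5×10⁴ pairs/sample. Monte-Carlo volumes use 10⁵–10⁶
samples depending on the tolerance required (standard errors are always
reported and assertions are phrased in units of them). Frequencies are
conserved to 1 part in 10⁹ before sampling; RPM sums are checked to
relative 10⁻⁶; superposition invariances to 10⁻⁹ Å. Degenerate inputs
fail loudly: empty count tables, non-positive CFU or culture times,
constant observables, collinear superposition selections and non-positive
Monte-Carlo sample counts are all rejections, not warnings.

## Known limitations

* Variant calling is strictly indel-intolerant by design; any length
  change discards the read.
* The fitness statistic is the plain ratio estimator — no shrinkage,
  error modeling or regression scoring.
* The toeprint model is linear with one anchor; constructs with
  non-uniform spacing need per-construct calibration.
* The overlap volume depends on the chosen atom selections and radii;
  both are exposed as arguments rather than fixed policy.
* MD trajectory generation, cryo-EM processing and wet-lab assays are out
  of scope; the geometry engine consumes coordinates, it does not create
  dynamics.
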