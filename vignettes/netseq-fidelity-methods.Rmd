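---
title: "Measuring transcription fidelity from NET-seq 3' ends: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transcription fidelity from NET-seq 3' ends: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netfidelity)
```

## The measurement

NET-seq (Native Elongating Transcript sequencing) captures RNAs still held by
transcribing RNA polymerase and sequences their 3'-proximal portion. Each read
is therefore a snapshot of one elongation complex (EC), and the read's last
base is the nucleotide the polymerase has just added. Comparing that base (and
the ten preceding it, roughly the RNA/DNA hybrid) against the DNA template
turns a NET-seq library into a direct assay of transcription fidelity: a
mismatch at the 3' terminus marks an EC that has just misincorporated, and the
fraction of reads with a terminal mismatch estimates the fraction of ECs in
the misincorporated state at steady state.

`netfidelity` implements this measurement end to end — a ground-truth
synthetic read generator, a 3'-anchored unique aligner, strain-variant
masking, the per-position substitution spectrum, hotspot and sequence-context
analysis, region-stratified rates, and an error-propagation model separating
biology from experimental noise — with tibble-in/tibble-out interfaces,
`tidy()`/`glance()` accessors and `autoplot()` methods throughout.

## Coordinate and orientation conventions

All internal coordinates are 0-based half-open; GFF3 and VCF writers convert
to their 1-based conventions at the file boundary, and BED matches the
internal convention directly.

Reads are kept in *transcript space*: written 5' to 3' with U as T, so the
last character is the nascent 3' terminus. Offsets count back from that
terminus — offset 0 is the terminal base, −1 the base before it, and the
default analysis window of 11 covers offsets 0…−10. For a minus-strand EC the
3' terminus maps to the *leftmost* genomic coordinate of the alignment
footprint, and template bases are complemented so that substitution labels
(e.g. `G>A`: template G read as A) are always template>read in transcript
space.

## The synthetic-data generator

`sim_config()` / `simulate_netseq()` generate a random genome (default 200 kb,
GC 0.5) with non-overlapping three-part gene models (5'UTR, CDS with length a
codon multiple, 3'UTR) on both strands, then sample ECs along transcripts with
log-normal per-gene abundances, and synthesize one read per EC (16–30 nt).
Five event layers are applied in biological order, each recorded in a truth
table:

1. **Misincorporation** at offset 0 with probability `misinc_fraction`
   (default 0.03), drawing the substituted base from a G>A-biased
   12-class spectrum (default mass 0.55 on G>A). An optional
   `hotspot_motif_boost` multiplies the probability at C(−1)G(0) template
   motifs to plant hotspots; the default boost is 1 (off), so hotspots arise
   only where coverage concentrates.
2. **Read-through** (T>C at offsets −1/−2, rate 0.002) mimicking rare
   extension past a mismatch.
3. **Reverse-transcription errors** (1e-4 per base).
4. **PCR errors** (4e-7 per base per cycle, 15 cycles).
5. **Sequencing miscalls** (1e-3 per base), which also draw their quality
   scores from a lower distribution (normal mean 22 sd 6, truncated to
   [2, 40]) than correct calls (mean 38 sd 2) — giving the Phred filter
   something real to do.

Optionally, homozygous strain-vs-reference variants are planted in
transcribed spans before reads are synthesized, so the variant-masking stage
has genuine targets. Every stage derives its RNG stream from the single run
seed, making whole runs byte-reproducible.

These defaults are the package's *study conditions*: 2×10^5 reads on 200 kb
gives roughly a thousand informative mismatches per percentage point of
injected signal, enough to separate a 3% from a 5% misincorporated-EC
fraction at a 99% binomial confidence level on one CPU in minutes. They are
not calibrated to any particular organism; the generator's realism is limited
to what the analysis consumes (per-base error layers, quality-score
separation, coverage heterogeneity) and deliberately omits ligation bias,
duplicated reads and indels.

## Alignment

The aligner (`align_reads()`, C++ core) is seed-anchored at the read's 3'
end: the 14-base suffix is the seed, because that end carries the signal and
must not be soft-clipped away. Candidate placements on either strand are
found exactly by the pigeonhole principle — the seed is cut into
`seed_mismatches + 1` parts, one of which must match exactly — and each
candidate is extended ungapped over the full read with no mismatch cap
outside the seed. Placements are ranked by total mismatches; any tie in the
best stratum rejects the read as multimapped (only uniquely mapping reads are
analysed). Any base pair involving N counts as a mismatch. Circular contigs
are handled by index padding so reads may span the origin.

The seed length is justified by `kmer_uniqueness()`: on random genomes at the
default scale, well over 99% of 14-mers are unique across both strands.
Ungapped alignment is sufficient because the generator (like the assay's
dominant error modes) produces substitutions, not indels; reads with indels
would simply fail the seed or accumulate mismatches and drop out.

## Spectrum, masking and the denominator

`extract_mismatch_events()` walks offsets 0…−10 of every accepted alignment.
A mismatch becomes an *event* only if neither base is N, the base call is at
least Phred 30 (99.9% accuracy; sub-threshold mismatches are discarded as
likely miscalls) and the position carries no called variant. The denominator
at each offset counts every aligned read with a non-N base there, regardless
of quality — discarding a low-quality mismatch treats the read as matched
rather than removing it, which keeps the rate a per-EC proportion. A
`quality_filtered_denominator` switch provides the stricter alternative.

Strain-vs-reference variants are called from a strand-pooled pileup
(`pileup()` + `call_variants()`: depth ≥ 10, alt fraction ≥ 0.8 — a
threshold caller suited to homozygous differences, which sit near fraction 1
while misincorporation noise stays far below) and all events at variant
positions are masked.

`positional_error_table()` reports the total mismatch rate per offset and the
same rate split over the 12 substitution classes;
`misincorporated_ec_fraction()` is the offset-0 total — the headline
percentage of ECs caught in the misincorporated state.

## Hotspots, context and regions

`call_hotspots()` groups offset-0 events by genomic location (strictly more
than 50 events at the default, per-substitution or pooled);
`threshold_sweep()` shows how signal concentrates as the per-position
threshold rises. `extract_context()` returns transcript-oriented windows
around hotspot positions (minus-strand windows reverse-complemented; linear
contigs truncate with N, circular contigs wrap), and
`position_frequency_matrix()` summarises them as a 4×width PFM — the numeric
core of a sequence logo. `region_rate_table()` stratifies distinct
misincorporated locations into translated (CDS), transcribed-untranslated
(UTR, plus introns in yeast mode) and other, normalised per 100 kb of
per-strand class length.

## The error-propagation model

Three experimental layers separate the nascent RNA from the base call.
Under a small-rate additive model they compose to a single per-base
experimental error probability

$$p_\mathrm{exp} = p_\mathrm{RT} + n_\mathrm{cycles}\,p_\mathrm{PCR} + p_\mathrm{seq}
                 = 10^{-4} + 15\times4\times10^{-7} + 10^{-3} = 1.106\times10^{-3},$$

neglecting cross terms (below 1e-6). A genuine mismatch hit by a superimposed
error stays mismatched with probability $f = 2/3$ (one of the three
alternative bases is the template), so the observed mismatch rate at an
offset is

$$r_\mathrm{obs} = r_\mathrm{true}\,(1 - p_\mathrm{exp}(1 - f)) + (1 - r_\mathrm{true})\,p_\mathrm{exp}.$$

`true_positive_fraction()` inverts this for $r_\mathrm{true}$ and reports the
percentage of observed mismatches that are genuine. At the printed wild-type
3' rate of 3% under the default budget:

```{r accuracy}
true_positive_fraction(0.03, error_budget())
```

— more than 96% of the observed 3' signal is biology, not artefact. Observed
rates at or below the noise floor $p_\mathrm{exp}$ clip to a true rate of
zero with a warning, which is exactly what interior offsets (−3…−10) of a
clean library should do.

## Worked example

```{r pipeline}
cfg <- pipeline_config(
  sim = sim_config(genome_length = 20000, n_genes = 6, n_ecs = 8000,
                   misinc_fraction = 0.05, variant_positions = 2),
  seed = 11)
rep <- run_pipeline(cfg, quiet = TRUE)
rep
glance(rep)
rep$error_table
rep$truth_comparison$injected_percent
```

Plots: `autoplot(rep$error_table)` for the positional spectrum,
`autoplot(rep$error_table, specific = TRUE)` for the 12-class facets,
`autoplot(rep$pfm)` for hotspot contexts and
`plot_threshold_sweep(rep$sweep)` for the sweep.

## Design decisions and resolved questions

* **Unique-only alignment**: a tie at the best mismatch stratum rejects the
  read rather than picking arbitrarily; fidelity percentages must not ride on
  coin-flip placements.
* **Strict hotspot threshold** (`> 50`, not `>= 50`): "more than the
  threshold" is applied literally and consistently between caller and truth
  comparison.
* **Truth consistency**: when several event layers hit the same base, the
  last layer's base is what the read shows; the truth table records all
  layers in order, so the final record per (read, offset) matches the
  emitted sequence exactly.
* **Zero-mass spectrum rows**: if the substitution spectrum assigns no mass
  to any substitution from some template base, ECs selected for
  misincorporation on that base are left unmodified rather than forced into
  an unrepresentable class (and are not flagged in the truth table).
* **k-mer uniqueness without canonicalisation**: instances are pooled over
  both literal strands, so a reverse-complement palindrome is never unique —
  matching how the aligner actually sees the genome.
* **Resumability**: `stages = list(simulate = FALSE)` reloads persisted
  FASTA/GFF3/BED/FASTQ/truth artifacts from `outdir` and reproduces the
  in-memory run exactly, so the expensive generation step can be shared
  across analyses.

## Limitations

The generator produces substitutions only (no indels, no ligation or PCR
duplication bias), gene models are non-overlapping, and the variant caller
targets homozygous differences only. The accuracy model is first-order in
the error rates; it is validated against a Monte-Carlo simulation of the
three layers in the test suite, where the additive approximation holds to
well within sampling error at the default rates.
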