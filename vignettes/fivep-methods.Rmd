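---
title: "Models and methods behind fivep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fivep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fivep)
```

## The measurement model

5P-Seq captures mRNA decay intermediates that carry a 5' monophosphate,
i.e. molecules already engaged by the 5'→3' exonucleolytic pathway. Because
the exonuclease trails the last translating ribosome, the 5' end of each
intermediate marks the upstream edge of ribosome protection: about 14 nt
upstream of the first nucleotide of the codon in the paused ribosome's
P-site. Aggregated over genes, this yields three diagnostic features:

* a peak at start-codon offset −14 (ribosomes paused at initiation),
* 3-nt periodicity along the ORF (elongating ribosomes),
* a peak 17 nt upstream of the stop codon (terminating ribosomes).

All `fivep` coordinates are 0-based transcript positions. Offset 0 on the
start anchor is the first nucleotide of the start codon; offset 0 on the
stop anchor is the first nucleotide of the stop codon; there *is* an
offset 0, and negative offsets lie upstream. This convention makes the
documented pause positions literal offsets (−14, −17). The CDS length is
stop-codon inclusive, so `start_offset − stop_offset = cds_len − 3` for
every position of a transcript.

## The degradome simulator

`simulate_degradome()` is a generative model of the library, not a
sequence simulator. Per transcript it builds an intensity vector over all
positions:

| component | weight | where | default |
|---|---|---|---|
| initiation pause | `w_init` | start offset `-p_offset` | 5 |
| elongation | `w_elong` per codon | `-p_offset + 3k`, `k = 1..cds/3-1` | 1 |
| termination pause | `w_term` | stop offset `-term_offset` | 5 |
| background | `w_bg` per nt | everywhere | 0.5 |

`p_offset` defaults to 14 nt (the ribosome protection length) and
`term_offset` to 17 nt. The termination peak is modelled independently of
the initiation geometry because the two pauses are observed as separate
features. The background weight is defined *per nucleotide* so its level
does not depend on transcript length; 0.5/nt against a per-codon
elongation weight of 1 makes background roughly two thirds of a typical
gene's mass, which puts per-gene 5'UTR window counts in the tens at the
default depth (200 genes × 100,000 molecules) — enough for most genes to
clear the 20-read ratio filter while leaving visible sampling noise, the
regime the window statistics are designed for.

Genotype effects enter as a multiplier `f_utr5` on all intensity strictly
upstream of the initiation-pause position (start offsets < −14), with an
extra `f_utr5_osr` for a designated osmotic-stress-response (OSR) gene
subset (10% of genes by default). Because the dS window [−14, 31) is left
untouched, the expected uSvsdS loading-ratio shift between an `f_utr5 = 2`
library and a wild type is exactly log2 2 = 1 — this is the ground truth
the parameter-recovery tests check. The multiplier is condition
configuration, not hard-coded biology: stress-dependent designs are
expressed by choosing multipliers per simulated library.

`n_reads` unique molecules are drawn multinomially from the normalized
intensities; each gets a uniform random UMI (8 nt by default) and
`1 + Geometric(pcr_dup_mean)` emitted copies — the simplest overdispersed
PCR duplication model, with the mean exposed. UMI collisions are allowed
by default (realistic: 4^8 = 65,536 UMIs against ~10^5 molecules);
`distinct_umis = TRUE` forces collision-free tags so deduplication can be
checked against the truth record exactly.

What the simulator does **not** emulate: nucleotide sequence (hence no
ligation or mappability bias), rRNA contamination, multimapping, isoform
ambiguity. Passing tests therefore demonstrate that the pipeline computes
its statistics correctly on data obeying the stated positional model —
not that the model captures every artefact of real libraries.

## Windows and loading ratios

The published window bounds ("uS between −60 and −15, dS −14 to 31,
ddS 32 to 77", each described as 45 nt) cannot all be 45 nt under any
single inclusive-bounds reading. `fivep` adopts half-open intervals on
the printed left bounds — uS = [−60, −15), dS = [−14, 31), ddS = [32, 77)
— which are exactly 45 nt each; the single-nucleotide gap at offset −15
between uS and dS is accepted and documented. On the stop anchor the
printed dE bound (−18) overlaps uE = [−62, −17); the default scheme uses
dE = [−17, 46) so the two windows partition cleanly. Whether the
termination-paused ribosome belongs to uE (as the figure legend says) or
to dE is genuinely ambiguous in the source material; a `literal`
preset exposes the printed bounds verbatim, and all bounds are
config-overridable.

A ratio `XvsY` is `log2(X/Y)`, with a pseudocount of 0.5 added to both
counts only when one is zero, and is reported only when `X + Y ≥ 20`
(`min_reads`). The filter is applied per ratio — a gene may pass uSvsdS
and fail uEvsdE — because the read floor concerns the two windows being
compared. Genes whose 5'UTR is shorter than 60 nt cannot host uS and are
excluded from uS-based ratios. Replicates are pooled by summing window
counts (`pool_window_counts()`) before ratios; per-replicate analysis is
available by applying `loading_ratios()` per table.

## Genotype comparison

The per-gene score is a *difference of log2 loading ratios*,
`score = ratio(mut) − ratio(wt)`, equivalently the log2 fold change of
the raw window ratios. This is the only dimensionally coherent reading of
a "log2 of a ratio of ratios" and is computed on the intersection of
genes passing the filter in both strains. `median_increment()` reports
the difference of distribution medians instead, which matches the shift
shown under cumulative-distribution plots; the two coincide only for
symmetric paired differences, so both are exposed and neither is derived
from the other. `cumulative_summary()` uses the standard sample median
(midpoint of the middle order statistics for even n).

`subset_shift_test()` wraps the Mann-Whitney U test: exact null
distribution when the smaller group has ≤ 8 observations and there are no
ties, otherwise the normal approximation with tie and continuity
correction. Two-sided by default — a one-sided alternative is available
but the conservative default is deliberate, since subset hypotheses are
usually formed after looking at genome-wide trends. Fully tied input
returns p = 1 by definition rather than a 0/0 normal statistic.

## The MS enrichment funnel

Protein abundance is estimated two ways from confident peptides: the
mean intensity of the three most intense peptides (top-3; fewer available
→ mean of those present, flagged), and peptide count divided by molecular
weight (emPAI-like). Each (strain × replicate × gel set × method) set is
log2-transformed and median-centred, which makes the whole funnel
invariant to per-sample global intensity scaling. The two count-based gel
sets (bait band, lane remainder) are combined by averaging the normalized
values present; intensity-based sets are kept separate, since a protein's
peptide intensities in the bait band and the remainder measure different
gel slices of the same sample.

Enrichment against the untagged strain uses an equal-variance two-sample
Student's t-test (Welch by flag) on proteins with values in at least two
tagged-strain replicates, without multiple-testing correction — the
funnel's output is a candidate list for orthogonal validation, so
controlling per-comparison error and validating downstream is the stated
design. Proteins absent from the untagged strain are tested against a
floor imputed at the 5th percentile of the untagged set and flagged
`imputed`; absence is informative (enriched proteins are often undetected
in controls) and dropping such proteins would bias the funnel against its
strongest hits. The final filters: *reproducibly enriched* = mean log2
ratio > 1 (2-fold) with p < 0.05 vs untagged; *preferential* = p < 0.05
in both bait strains and log2 ratio > 1.5 (3-fold) vs the untagged strain
and vs each control strain. A protein qualifies if any quantification
unit passes (`method_mode = "either"`, the default; `"both"` requires the
count-based unit and an intensity-based unit to agree).

The MS simulator draws peptide counts as Poisson with rate ∝ MW/12 and
log-normal intensities, spikes `effect_log2` into the bait strains for a
chosen truth set, and includes per-sample scaling noise. At the default
design (500 proteins, 10 spiked at log2 effect 3, 3 replicates) the
funnel recovers at least 8 of 10 spiked proteins with at most 1 false
positive in each of 20 test seeds.

## Assay calculators

* `pulldown_enrichment()` / `mrna_pair_ratio()`: pure ratio algebra on
  qPCR relative quantities, with domain checks; scale-invariance under
  common positive rescaling is asserted in the tests.
* `relative_expression()`: efficiency-corrected ΔΔCt, `E^(−ΔΔCt)`,
  default E = 2 with per-primer override (standard-curve efficiencies are
  rarely published; E is exposed rather than assumed silently).
* `half_life()`: least squares on ln(abundance) vs time;
  `t½ = ln 2 / (−slope)`, SE by the delta method
  (`ln 2 · SE(slope)/slope²`). Non-negative slopes flag the transcript
  `stable` with infinite half-life rather than a negative number.
* `translation_efficiency_ratio()`: trapezoid AUC of the protein curve to
  its plateau divided by trapezoid AUC of the mRNA curve to a fixed 60-min
  horizon, mutant over wild type. The source material gives no plateau
  rule, so one is defined here: the first time point from which the curve
  stays within a 5% band of its running maximum (band configurable, the
  detected plateau time is reported). A curve flat from its first point
  "plateaus" immediately and would integrate to zero, so its AUC falls
  back to the full curve range. The mRNA horizon is interpolated linearly
  when it falls between sampled time points.
* `pfm_ratio()`: polysomal over sub-polysomal totals; the default
  fraction convention is sub-polysomal {1, 2}, polysomal {3,…,8}. Both
  area-under-trace and per-fraction qPCR quantities are acceptable
  inputs; the caller chooses what the quantities mean.

## Numerical and design choices

* Deduplication key: per-gene (5' position, UMI). With 8-nt UMIs and
  ~500 molecules per gene the within-position collision risk is small but
  nonzero; the distinct-UMI simulator mode exists precisely to separate
  collision loss from code error in tests.
* rpm denominator: deduplicated mapped reads, since every downstream
  count is deduplicated.
* Metagene aggregation: pooled sum of per-gene rpm (no per-gene
  normalization) by default, matching pooled-signal plots; a
  `per_gene = TRUE` variant weights genes equally for sensitivity
  analysis. No coverage floor is applied to metagenes — the 20-read
  filter belongs to per-gene ratios only.
* Reading frame: `offset mod 3` relative to the start codon in both the
  5'UTR and CDS windows (80 nt each), one consistent rule; elongation
  geometry puts CDS reads in frame 1 under this convention.
* BAM ingestion takes primary alignments with MAPQ ≥ 1 (configurable),
  excluding typical multimappers; the 5' end is strand-aware (rightmost
  aligned base on the minus strand), because the 5'P position must be the
  biological 5' end.
* GTF loading treats CDS features as stop-exclusive when `stop_codon`
  features are present (ensembl convention) and stop-inclusive otherwise;
  multi-exon transcripts are concatenated in transcript orientation.
  Isoform resolution is out of scope (one model per transcript id).

## Problem sizes

The shipped tests exercise the full pipeline at the simulator defaults
(200 genes, 100,000 unique molecules) for single-run geometry checks, and
20-seed batteries at the same depth for parameter recovery (Δmedian of
uSvsdS within ±0.15 of 1.0), OSR shift detection (power and type-I), and
the MS funnel (recovery/false positives). Unit tests use 3-gene fixtures
where exactness matters. These sizes were chosen so the whole suite
completes in minutes while keeping the multinomial sampling noise in the
regime the filters were designed for.

## Known limitations

* No genomic-alignment projection across exon junctions at read level:
  alignments are expected in transcript space (or BED with transcript
  names); the annotation module handles multi-exon *models*, not spliced
  read placement.
* The simulator's uniform background and fixed pause weights are
  conveniences, not biological claims; no quantitative occupancy model is
  available to emulate.
* The funnel's imputation floor (5th percentile) is a pragmatic choice;
  results for proteins absent from controls should be read as "at least
  this enriched".
* GO enrichment itself is out of scope: `rank_for_go()` exports ranked
  lists for external tools.
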