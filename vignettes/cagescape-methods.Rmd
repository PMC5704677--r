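---
title: "Methods: CAGE promoter landscapes, cross-species projection and annotation rescue"
author: "cagescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAGE promoter landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

CAGE (Cap Analysis of Gene Expression) sequences the capped 5' ends of
transcripts, so each uniquely mapped read marks a transcription start
site (TSS) at single-base resolution. In well-annotated genomes this
mostly re-finds known promoters; in sparsely annotated genomes (the
motivating cases are dog and rat) the same data can *refine* gene
models: a cluster of CAGE signal with no nearby annotated TSS is either
noise or a promoter the annotation missed. `cagescape` implements that
entire workflow — CTSS quantification, promoter (peak) calling,
gene-model association, cross-species projection of a well-characterised
reference peak set through genome-alignment chains, and the "Rescued
CAGE Peak" (RCP) procedure that assigns genes to un-annotated peaks via
orthology — together with a seeded synthetic-data generator so that
every stage is testable offline.

## CTSS quantification

Alignment records are filtered with the conventional criteria: mapping
quality at least 20 (`samtools view -q 20` semantics, i.e. MAPQ >= 20;
the informal "q>20" gloss found in prose descriptions is the same
filter), exclusion of secondary and QC-fail records (flag mask 768),
exclusion of unmapped records, and sequence identity of at least 85%
computed as `1 - NM/aligned_length` where an `NM` edit-distance tag is
present. Records lacking `NM` pass the identity filter with a one-time
warning, since identity cannot be reconstructed from coordinates alone.
Each retained record contributes one tag at its 5' end: the leftmost
aligned reference base on `+`, the rightmost on `-` (bamToBed
semantics; soft-clip reconstruction is out of scope). Counts are kept
strictly per strand at 1 bp resolution; the canonical record name is
`chrom:start..end,strand` with 0-based half-open coordinates, the
dialect used throughout FANTOM-style CTSS and peak files. Expression is
scaled as tags per million (TPM): `count * 1e6 / library_total`, with
the raw library total as denominator.

## Peak calling

The reference method (decomposition peak identification, DPI) clusters
continuous composite signal genome-wide and then decomposes clusters
across samples with an ICA-based model. Re-implementing DPI exactly is
explicitly out of scope; `cagescape` substitutes a documented,
parameterised two-step procedure with the same interface and the same
published thresholds:

1. **Clustering** (`cluster_ctss`): same-strand CTSS positions whose
   successive gaps are at most `max_gap` (default 20 bp, matching the
   reported 10–30 bp modal peak width) merge into candidate intervals.
2. **Decomposition** (`decompose_cluster`): the pooled per-base signal
   is smoothed with a Gaussian kernel (`smooth_sd` 5 bp) and split at
   local minima lying below `valley_fraction` (0.1) of the smaller
   flanking maximum, provided the maxima are at least
   `min_subpeak_gap` (10 bp) apart. Splitting conserves signal exactly:
   each CTSS position lands in exactly one sub-interval.

Tiering applies the published thresholds literally, reading "minimum"
as `>=`: a sub-interval is a **permissive** peak iff some sample has a
single position with at least 3 counts; it is additionally **robust**
iff some sample has a single position with at least 10 counts *and*
at least 1 TPM at that same position in that same sample (the joint
condition is evaluated within one sample, our reading of "in a single
position in at least one sample"). Peaks are trimmed to the span of
their CTSS positions. Downstream analyses use the robust tier, as the
source study does.

## Gene association and genomic context

A peak is associated with a gene model iff it overlaps, on the same
strand, the 1 kb window centred on the gene's 5' end — implemented as
the half-open `[tss - 500, tss + 500)`; whether the source procedure
closed the right end is unstated, and a 1 bp convention difference is
immaterial at these scales. Any overlap suffices (no minimum fraction
is published). Association runs per annotation set (e.g. Ensembl,
RefSeq, Augustus...), and `annotation_breakdown` bins peaks by the
number of sets hit; bin 0 is the un-annotated class that feeds the
rescue procedure. `classify_genomic_feature` assigns one label per peak
by fixed precedence — promoter > 5'UTR > exon > intron > TTS >
CpG-island > repeat > intergenic — with the promoter window spanning
1000 bp upstream to 500 bp downstream of a TSS. The precedence order is
our documented choice; the reference used HOMER, whose internal
ontology is not reproduced, so genomic-context tables are comparable
qualitatively, not numerically.

## Promoter architecture

TATA presence is scored by scanning a position-frequency matrix over a
strand-oriented window from 500 bp upstream to 200 bp downstream of the
peak's 5' boundary, as log-odds against a uniform background with a
0.01 pseudocount. The default threshold is 60% of the maximal
attainable score — the HOMER motif file's own cutoff is not published,
so this is a configurable package choice. CpG islands are detected with
Gardiner–Garden-style criteria (window 200 bp, GC >= 0.5,
observed/expected CpG >= 0.6, qualifying windows merged), standing in
for the UCSC track that exists only for reference genomes. Peaks are
classed TATA-only / CpG-only / both / neither, and the TATA-only vs
CpG-only width comparison uses Welch's t (the source says only
"Student's t-test ... default parameters", and R's default *is* the
Welch form).

## Cross-species projection and matching

Intervals are projected through UCSC chain files by exact block
arithmetic. Each interval is walked through candidate chains in
decreasing score order and maps through the first chain on whose
aligned blocks at least `min_match` of its bases land (0.95, the
liftOver default); the projected interval is the span of the mapped
bases, with minus-strand query coordinates converted to the plus
strand and the interval strand flipped. Taking the highest-scoring
chain rather than reproducing net/chain subtleties is a documented
simplification. A projected source peak then *matches* a destination
peak iff both are on the same strand and both boundary shifts are at
most 50 bp — the stricter both-ends reading of "within 50 bp both
upstream and downstream", consistent with the cited observation that
promoter architecture conservation decays beyond ~70 nt. Among several
candidates the smallest `|Δstart| + |Δend|` wins, ties to the leftmost.
Source peaks are pre-filtered to those expressed (>= 1 TPM and nonzero)
in at least one sample of a matching cell type. Chain inversion is
provided for round-trip checks; an exact round trip is only defined for
intervals whose forward image is gap-free (an interval spanning an
insertion maps fully forward, but its image contains unaligned bases).

## Rescued CAGE Peaks

A destination peak is rescued iff (a) it has zero associations in every
annotation set, (b) it matches a projected source peak, (c) that source
peak is annotated (by default with the first/most complete source set),
(d) orthology maps one of its genes to a destination gene, and (e) some
model of that gene lies within 10 kb of the peak. Distance is the
minimum gap to the gene's full model span, not its TSS — unspecified in
the source, configurable here — and is zero for overlap. When several
ortholog routes qualify, all are reported, nearest first. Rescue is
monotone in the distance threshold and invariant to input ordering.
`rcp_summary_stats` reports the descriptive statistics used to
characterise rescued sets: median peak width, median rescued-gene
length, the fraction of rescued genes whose transcription start equals
their coding start ("ORF-like" predicted models, a diagnostic for
annotations that record an ORF start rather than a real TSS),
peaks-per-gene counts (multiple RCPs inside one gene suggest unknown
isoforms), and overlap with a user-supplied TF list.

## QC and normalization

TMM scaling factors, Spearman matrices and classical MDS are
re-implemented rather than delegated, so that the test suite can hold
them against independent oracles (edgeR, `stats::cor`,
`stats::cmdscale`). TMM follows the standard definition: gene-wise
log-ratios against a reference sample (the one whose upper-quartile of
scaled counts is closest to the mean), double trimming (30% on M, 5% on
A), inverse-variance weighting, factors rescaled to geometric mean 1.
One property worth stating honestly: because the precision weights
depend on sequencing depth, scaling one sample's counts by a constant
is *not* exactly neutral for the other samples' factors — edgeR behaves
identically — so the scale-invariance property is asserted at 1%
rather than machine precision. Spearman uses midranks and a hand-rolled
Pearson on rank vectors; constant columns give `NA` with a warning. MDS
distances are the root-mean-square of the `top_n` (500) largest
absolute log2 fold-changes between two samples on `log2(x + 0.5)`
(the prior count handles zeros; the source publication does not state
its convention), embedded by Torgerson double-centring; coordinates
are unique only up to sign and rotation.

## The synthetic world

The generator emits a complete fixture bundle from one seed: two toy
genomes linked by a chain, gene models over several pseudo annotation
sets, CpG islands, a TATA PWM, a "reference species" peak set with
expression, per-sample CTSS BED files and matching SAM streams, and a
ground-truth table. Its defaults are the stated world of the test
suite:

* **Promoter shapes.** Tag positions are drawn from a discretised
  Gaussian around the true TSS — SD 2 bp truncated at ±5 bp for sharp
  promoters, SD 25 bp at ±75 bp for broad ones. The source reports
  shape classes and width statistics but no generative model; this is
  the simplest model reproducing sharp (~10 bp) vs broad (~150 bp)
  called widths.
* **Expression.** Per-promoter means are log-normal
  (`meanlog = log(300)`, `sdlog = 1.2` — a spread of a few orders of
  magnitude, typical of promoter expression); cell-type effects are
  log-normal multipliers (`sdlog` 0.8) shared within replicate groups;
  replicate noise is negative binomial with size 40, calibrated so
  promoter-level replicate Spearman sits near the reported 0.97.
  Background noise is uniform at 1e-4 tags/bp/sample.
* **Sequence.** Background base composition is 40% GC, safely below
  the CpG-island threshold. Sharp promoters get the TATA consensus
  planted with its start 35 bp upstream of the TSS (within the
  reported 30–35 bp preference window); since a called sharp peak's 5'
  boundary sits ~0–5 bp upstream of the mode, scan offsets anchored at
  the boundary concentrate in (−35, −30]. Broad promoters sit inside
  an emitted 300 bp CG-rich island (GC 0.7).
* **The second species.** The destination genome differs by a Poisson
  process of 1–10 bp indels (5e-4 events/bp), kept 200 bp clear of
  TSSs so that true peak pairs stay within the 50 bp matching rule,
  plus one wholly reverse-complemented chromosome to exercise
  minus-strand chains. The emitted chain describes the edit exactly.
* **Rescue candidates.** A configurable fraction of destination genes
  is dropped from every destination annotation set but kept in the
  orthology table, and given a displaced (2–6 kb) ORF-like "predicted"
  model used for rescue distances only — mirroring the real situation
  where a predicted gene model exists near the peak but its recorded
  TSS is more than 1 kb away.

What a green suite does and does not establish: it shows the
implementation is faithful to its stated rules on data with known
truth — exact threshold semantics, oracle-identical projection,
sound and complete rescue on engineered candidates. It does not
establish that the simplified valley decomposition reproduces DPI's
exact boundaries on real FANTOM data, nor that real genomes' repeat
content, mappability or chain complexity behave like the toy world.

## Numerical and degenerate-input choices

Thresholds are inclusive (`>=`) throughout, matching "minimum"/"within"
wording. Empty inputs yield empty-but-well-formed outputs (an empty
rescue set, a zero-row peak table); an all-zero expression column is an
error naming the sample; constant columns in correlation are `NA` with
a warning; scan windows are truncated at chromosome ends with a
warning; TATA score ties resolve to the offset nearest the anchor;
matching ties resolve to the leftmost destination start; MDS requires
`dims < n_samples`. All randomness flows from the single configuration
seed through one RNG stream in a fixed draw order, so equal seeds give
byte-identical fixture bundles and the pipeline itself draws no random
numbers at all.

## Known limitations

Valley decomposition is a stand-in for DPI, not a reimplementation;
per-sample decomposition is not attempted. Identity filtering needs an
`NM` tag; BED-level reprocessing cannot recover it. Chain selection
ignores net files. Enhancer (bidirectional) calling is out of scope, as
it was in the source study at this sample count. The genomic-context
classifier uses a fixed precedence rather than HOMER's ontology, so its
output is comparable only qualitatively.
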