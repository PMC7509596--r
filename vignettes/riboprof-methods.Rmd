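---
title: "Methods: Ribo-seq QC, P-site assignment and quantification in riboprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Ribo-seq QC, P-site assignment and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboprof)
```

## The problem

Ribosome profiling sequences the ~20–30 nt mRNA fragments protected by
translating ribosomes from nuclease digestion (ribosome-protected
fragments, RPFs). Paired with total-RNA sequencing from the same sample,
it supports quantitative statements about translation: which coding
sequences are being translated, at what ribosome density, and with what
efficiency relative to mRNA abundance. Before any of those statements can
be trusted, a library has to pass a set of structural validations that
distinguish genuine footprints from RNA background, and the quantification
has to follow conventions that make replicates and assays comparable.
`riboprof` implements that downstream layer for libraries already aligned
to a transcriptome reference. Upstream preprocessing — adapter clipping,
rRNA depletion, alignment — is deliberately out of scope: the toolkit
ingests transcriptome-space SAM/BAM.

## Coordinate model

All positions are 0-based, half-open and transcript-relative; GFF3's
1-based closed intervals are converted once, at the parser boundary, so no
downstream arithmetic ever re-converts. Each transcript model partitions
`[0, length)` into three contiguous intervals: `[0, utr5_len)` is the
5′UTR, `[utr5_len, utr5_len + cds_len)` the CDS, the remainder the 3′UTR.
Multi-exon, minus-strand annotations are projected into this space by
cumulating exon widths along the transcript strand.

Two policies are worth stating because annotation practice varies:

- **Isoforms.** Genes are quantified through a single representative
  transcript: longest CDS, ties broken by longest transcript, then
  lexicographically smallest id. The choice is deterministic and recorded
  in the transcript set's gene index.
- **Incomplete CDSs.** A CDS whose length is not a multiple of 3 cannot
  define a reading frame. Such transcripts are retained for length and
  region QC but their footprints carry an undefined frame and are excluded
  from periodicity analysis. The condition downgrades a flag; it never
  aborts a run.

## P-site and A-site assignment

The P-site is placed at a fixed offset from the footprint's 5′ end —
12 nt by default, applied to all fragment lengths in both windows — and
the A-site one codon further 3′ (`a_site = p_site + 3`), reflecting an
initiating ribosome holding the start codon in the P-site and the second
codon in the A-site. The reading frame is `(p_site − utr5_len) mod 3`
when the P-site lies in a complete CDS. A per-length offset table is
accepted for generality, but no data-driven offset learning is performed:
the metagene profile is the user's tool for verifying that the fixed
offset fits their protocol (the initiation peak must sit at −offset).

Footprints whose P- or A-site would fall beyond the transcript are
flagged invalid and tallied rather than dropped silently; every stage
reports its skip and flag counts.

## Validation analyses

- **Fragment lengths.** Genuine RPF libraries concentrate in narrow
  length modes (here 20–22 and 27–29 nt are retained for analysis);
  RNA-seq is flatter.
- **Region distribution.** Footprints are assigned to 5′UTR/CDS/3′UTR by
  their **P-site**; RNA-seq reads by their **5′ end**, since they have no
  P-site. The anchoring choice matters: footprints should be nearly
  all-CDS, while RNA-seq occupancy tracks region lengths — with typical
  mRNA geometry roughly 60% CDS.
- **Metagene profile.** 5′-end positions relative to the first nucleotide
  of the start codon, per length class, over a configurable window
  (default [−40, +60]; the window is a reporting choice, not a model
  parameter). Profiles are reported as raw counts and within-class
  fractions; averaging across libraries is a thin reporting layer the
  user applies to per-library outputs.
- **Frame distribution / periodicity score.** Fraction of P-sites per
  codon position and its per-class maximum: 1/3 for frame-uniform data,
  approaching 1 for phased footprints.

## Quantification and reproducibility

Gene counts keep footprints whose A-site lies in the CDS at least 20 nt
downstream of the start codon (inclusive boundary: exactly 20 counts).
This trims the initiation peak, whose occupancy reflects start-codon
kinetics rather than elongation. Then

$$\mathrm{RPKM} = \frac{\text{count} \times 10^9}{\text{cds\_len} \times \text{library\_size}}$$

with `library_size` defined as the number of reads surviving ingestion
and length filtering for a Ribo-seq library, and all ingested reads for
RNA-seq. The definition is a convention, not a law; it is recorded on
every expression table so alternates are comparable. The same downstream
filter is applied to RNA-seq when computing CDS RPKM for matched
comparisons. RPKM is kept at full float precision internally and rounded
to 6 significant digits only when written to TSV.

Translation efficiency is the per-gene ratio `RPKM_ribo / RPKM_rna`,
defined where the denominator is positive; genes failing that are omitted
and tallied.

Replicate reproducibility is assessed per pair of libraries: the common
subset of genes with RPKM ≥ 10 **in both members** (resolved per pair,
not across all libraries), then Pearson and Spearman coefficients on the
RPKM vectors. Whether Pearson should be taken on raw or log RPKM is a
genuinely open convention; the package computes raw by default, offers
`log10 = TRUE`, and records the choice in the report, asserting neither
as canonical. Both coefficients are delegated to `stats::cor` (Spearman
as Pearson on mid-ranks); the test suite checks them against independent
direct-formula oracles.

## The simulator

Every pipeline stage is validated against a footprint simulator whose
ground truth is known per read. It emulates the features of real
Ribo-seq/RNA-seq data that the pipeline's logic depends on:

- a synthetic transcriptome whose CDSs start with ATG, end with a single
  terminal stop codon, and whose geometry defaults to 100–200 nt 5′UTRs,
  150–600 codon CDSs and 400–800 nt 3′UTRs — chosen so the expected
  RNA-seq CDS occupancy is about 60%, the regime typical of mammalian
  transcriptomes;
- log-normal gene abundances (meanlog 2, sdlog 1) shared across
  replicates, with optional per-gene ribosome-loading multipliers for
  translation-efficiency experiments;
- a bimodal footprint length mixture with 40% of mass in 20–22 nt and
  60% in 27–29 nt;
- P-sites drawn uniformly over CDS codons (an optional per-codon dwell
  hook exists), 5′ ends placed at `p_site − 12` with probability equal to
  the periodicity fidelity (default 0.9) and jittered ±1 nt otherwise;
- RNA-seq 5′ ends uniform over **all** transcript positions with fragment
  lengths clipped at the 3′ terminus. This choice makes expected region
  occupancy track region lengths exactly; requiring whole fragments to
  fit would depress the 3′UTR fraction by roughly the mean read length
  divided by transcript length.

Reads are emitted pre-aligned as sense-strand SAM against the transcript
reference (an optional FASTQ writer exists for demonstrations with an
external aligner), removing alignment from the test loop. One seed drives
everything; replicate libraries derive sub-seeds deterministically from
`seed + library index`, so outputs are byte-reproducible.

What the simulator does **not** emulate — and what passing tests therefore
do not show about real data: sequencing errors, adapter or rRNA
contamination, multi-mapping and isoform ambiguity, codon-usage–dependent
dwell times (unless supplied via the hook), length-dependent P-site
offsets, and nucleotide-composition biases of library preparation. Tests
against the simulator validate the pipeline's arithmetic and contracts,
not the biology of any particular dataset.

## Numerical and degenerate-input choices

- Region fractions are exact ratios of integer counts; empty inputs yield
  zero counts with `NA` fractions rather than 0/0.
- Degenerate correlations (zero variance; all-tied vectors) return `NA`
  with a warning, and replicate pairs with fewer than 3 common genes are
  reported as undefined rows, not dropped.
- Window and threshold boundaries are inclusive throughout (length
  windows, the ≥ 20 nt A-site filter, the RPKM ≥ 10 cutoff).
- Uniform integer draws over configuration ranges use an explicit
  `lo + floor(u · (hi − lo + 1))` construction, immune to the scalar
  expansion of `sample()` for degenerate ranges.
- Simulated reads that would overhang a transcript end (e.g. a 5′ end
  before position 0 after subtracting the offset) are redrawn and
  tallied.

## Problem sizes

The test suite exercises the pipeline at the scales its statistical
assertions need: 50,000 reads for offset recovery and frame fractions
(binomial standard error ≈ 0.0013 against a ±0.01 assertion), 10,000
reads for region fractions (±0.02), 10^6 reads for abundance-rank
recovery and replicate correlation (where adjacent configured abundances
differ by ~39% and the rarest gene still receives hundreds of reads, so
exact rank recovery is expected, not hoped for), and 10^5 reads for the
chi-square goodness-of-fit check of the sampling law (α = 0.001 under a
fixed seed).

## Known limitations

- Single fixed P-site offset by default; protocols with strongly
  length-dependent offsets should pass `offset_by_length`.
- One representative transcript per gene; isoform-level quantification is
  out of scope.
- Transcriptome-space alignments only; spliced genomic projection is not
  performed, and reverse-strand alignments to transcripts are counted and
  skipped rather than rescued.
- No deduplication (none is assumed by the counting conventions) and no
  differential-expression layer; expression tables are plain data frames
  that feed naturally into dedicated statistical packages.
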