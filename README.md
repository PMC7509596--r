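# riboprof

Downstream analysis of ribosome profiling (Ribo-seq) experiments aligned to
a transcriptome reference, for researchers who have adapter-clipped,
rRNA-depleted and transcriptome-aligned their libraries and now need the
standard validation and quantification layer:

- **Transcript models** from GFF3 + FASTA: 5′UTR / CDS / 3′UTR extents in
  0-based, half-open transcript coordinates.
- **Footprint ingestion** from SAM/BAM: primary, sense-strand alignments
  reduced to `(transcript, 5′ end, length)`, with fragment-length
  filtering to the ribosome-protected windows 20–22 and 27–29 nt.
- **P-site assignment** with a fixed 5′-end offset (12 nt by default):
  `p_site = five_prime + 12`, `a_site = p_site + 3`, reading frame
  `(p_site − utr5_len) mod 3` inside the CDS.
- **QC**: fragment-length histograms, read-region distributions (P-site
  anchored for Ribo-seq, 5′-end anchored for RNA-seq), start-codon
  metagene profiles per length class, and triplet-periodicity /
  reading-frame summaries.
- **Quantification**: gene-level CDS counts keeping reads whose A-site is
  ≥ 20 nt downstream of the start codon, then
  `RPKM = count · 10⁹ / (cds_len · library_size)`, and translation
  efficiency `TE = RPKM_ribo / RPKM_rna`.
- **Reproducibility**: Pearson and Spearman correlations between replicate
  libraries over the per-pair common subset of genes with RPKM ≥ 10.
- **Simulation**: a footprint simulator with full ground truth (synthetic
  transcriptome, bimodal length mixture, configurable periodicity
  fidelity, log-normal abundances, ribosome-loading multipliers) so every
  stage is testable without external data.

## Worked example

```r
library(riboprof)

cfg <- sim_config(n_genes = 20, n_reads = 10000, seed = 101)
tx  <- simulate_transcriptome(cfg, "sim")
rb  <- simulate_ribo(cfg, tx, sam_path = "sim/ribo.sam")

txs   <- load_transcripts(tx$gff3_path, tx$fasta_path)
reads <- read_alignments("sim/ribo.sam", txs)
kept  <- filter_by_length(reads, rpf_windows())
sites <- assign_sites(kept, txs, offset = 12)

frame_distribution(sites)
#>   length_class frame count   fraction
#> 1        20-22     0  3648 0.89830091
#> 2        20-22     1   180 0.04432406
#> 3        20-22     2   233 0.05737503
#> 4        27-29     0  5315 0.89523328
#> 5        27-29     1   307 0.05170962
#> 6        27-29     2   315 0.05305710
```

About 90% of P-sites fall in frame 0 in both length classes — the
simulator's periodicity fidelity is 0.9, and the pipeline recovers it.
The remaining ~5%/5% are the ±1 nt jittered footprints. Quantify and
correlate replicates the same way:

```r
tab <- gene_expression_table(sites, txs)       # gene_id, cds_len, count, rpkm
head(tab, 2)
#>    gene_id cds_len count     rpkm
#> 1 gene0001    1398  1169 83619.46
#> 2 gene0002    1743   800 45897.88
replicate_report(list(rep1 = tab, rep2 = tab))  # pearson/spearman per pair
```

A shell front-end wrapping the same functions ships in
`inst/scripts/riboprof` (subcommands `simulate`, `lengths`, `qc`,
`quantify`, `correlate`, `pipeline`), and `run_pipeline()` chains
QC → quantification → correlation over whole libraries, writing TSVs and
a JSON run manifest.

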