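#' Configuration for the synthetic footprint simulator
#'
#' Bundles every parameter of the synthetic transcriptome and read
#' generator. Defaults emulate the characteristics of a typical human
#' Ribo-seq library aligned to a transcriptome: a bimodal footprint length
#' mixture concentrated at 20–22 and 27–29 nt, a fixed 5'-end P-site
#' offset of 12 nt, strong frame-0 periodicity, CDS lengths much larger
#' than UTR lengths, and log-normal gene abundances shared across
#' replicates.
#'
#' @param n_genes number of genes (one transcript each).
#' @param utr5_range,utr3_range inclusive nt ranges for UTR lengths.
#' @param cds_codons_range inclusive range for CDS length in codons
#'   (excluding neither start nor stop; total CDS nt = 3 * codons).
#' @param abundances optional explicit per-gene abundance vector;
#'   otherwise drawn log-normally.
#' @param abundance_meanlog,abundance_sdlog log-normal abundance
#'   parameters (natural-log scale).
#' @param ribo_length_mix named probability vector over footprint lengths;
#'   must sum to 1.
#' @param psite_offset 5'-end to P-site offset in nt used when placing
#'   reads (default 12).
#' @param periodicity_fidelity probability that a footprint 5' end lands
#'   exactly at `p_site - psite_offset`; the remainder is jittered +/-1 nt
#'   (split evenly), degrading frame phasing.
#' @param dwell_weights optional function `(n_codons) -> numeric weights`
#'   giving relative per-codon P-site occupancy; `NULL` means uniform.
#' @param loading_multipliers optional per-gene ribosome-loading
#'   multipliers (recycled to `n_genes`), for translation-efficiency
#'   experiments.
#' @param rna_length_range inclusive nt range of RNA-seq fragment lengths.
#' @param n_reads reads per simulated library.
#' @param seed integer seed; every simulator output is a deterministic
#'   function of the configuration including the seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 100L,
                       utr5_range = c(100L, 200L),
                       cds_codons_range = c(150L, 600L),
                       utr3_range = c(400L, 800L),
                       abundances = NULL,
                       abundance_meanlog = 2,
                       abundance_sdlog = 1,
                       ribo_length_mix = c("20" = 0.12, "21" = 0.16,
                                           "22" = 0.12, "27" = 0.18,
                                           "28" = 0.24, "29" = 0.18),
                       psite_offset = 12L,
                       periodicity_fidelity = 0.9,
                       dwell_weights = NULL,
                       loading_multipliers = NULL,
                       rna_length_range = c(20L, 32L),
                       n_reads = 50000L,
                       seed = 42L) {
  stopifnot(n_genes >= 1L,
            all(utr5_range >= 0L), all(utr3_range >= 0L),
            all(cds_codons_range >= 2L),
            utr5_range[1] <= utr5_range[2],
            utr3_range[1] <= utr3_range[2],
            cds_codons_range[1] <= cds_codons_range[2],
            periodicity_fidelity >= 0, periodicity_fidelity <= 1,
            psite_offset >= 0L, n_reads >= 0L)
  if (abs(sum(ribo_length_mix) - 1) > 1e-9)
    stop("ribo_length_mix must sum to 1", call. = FALSE)
  if (!is.null(abundances) && length(abundances) != n_genes)
    stop("abundances must have length n_genes", call. = FALSE)
  cfg <- list(n_genes = as.integer(n_genes),
              utr5_range = as.integer(utr5_range),
              cds_codons_range = as.integer(cds_codons_range),
              utr3_range = as.integer(utr3_range),
              abundances = abundances,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              ribo_length_mix = ribo_length_mix,
              psite_offset = as.integer(psite_offset),
              periodicity_fidelity = periodicity_fidelity,
              dwell_weights = dwell_weights,
              loading_multipliers = loading_multipliers,
              rna_length_range = as.integer(rna_length_range),
              n_reads = as.integer(n_reads),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# uniform integers in [lo, hi]; immune to sample()'s scalar expansion
.sample_range <- function(range, n) {
  range[1] + floor(stats::runif(n) * (range[2] - range[1] + 1L))
}

# the 61 sense codons (stops excluded so simulated CDSs have a single
# in-frame stop, the terminal one)
.sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all <- apply(expand.grid(bases, bases, bases), 1, paste0, collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
}

#' Generate a synthetic transcriptome
#'
#' Draws per-gene UTR lengths, CDS lengths (in codons) and abundances from
#' the configuration and writes the transcriptome to disk as FASTA +
#' GFF3, together with a plain-text specification table recording the
#' ground truth. Every CDS begins with ATG, ends with a stop codon and
#' contains no internal in-frame stop; UTR nucleotide content is uniform
#' random. Output is a deterministic function of the configuration.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return list with `fasta_path`, `gff3_path`, `spec_path`, the `spec`
#'   data.frame (`transcript_id`, `gene_id`, `utr5_len`, `cds_len`,
#'   `utr3_len`, `length`, `abundance`, `loading`), the `sequences`
#'   (`DNAStringSet`) and the `config`.
#' @export
simulate_transcriptome <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(config$seed, {
    n <- config$n_genes
    utr5 <- .sample_range(config$utr5_range, n)
    codons <- .sample_range(config$cds_codons_range, n)
    utr3 <- .sample_range(config$utr3_range, n)
    abund <- config$abundances
    if (is.null(abund))
      abund <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
    loading <- config$loading_multipliers
    loading <- if (is.null(loading)) rep(1, n) else rep_len(loading, n)
    sense <- .sense_codons()
    stops <- c("TAA", "TAG", "TGA")
    seqs <- character(n)
    for (i in seq_len(n)) {
      cds <- paste0("ATG",
                    paste(sample(sense, codons[i] - 2L, replace = TRUE),
                          collapse = ""),
                    sample(stops, 1L))
      seqs[i] <- paste0(
        paste(sample(c("A", "C", "G", "T"), utr5[i], replace = TRUE), collapse = ""),
        cds,
        paste(sample(c("A", "C", "G", "T"), utr3[i], replace = TRUE), collapse = ""))
    }
  })
  spec <- data.frame(
    transcript_id = sprintf("tx%04d", seq_len(config$n_genes)),
    gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
    utr5_len = as.integer(utr5),
    cds_len = as.integer(codons * 3L),
    utr3_len = as.integer(utr3),
    stringsAsFactors = FALSE
  )
  spec$length <- spec$utr5_len + spec$cds_len + spec$utr3_len
  spec$abundance <- abund
  spec$loading <- loading

  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- spec$transcript_id
  fasta_path <- file.path(out_dir, "transcripts.fa")
  gff3_path <- file.path(out_dir, "annotation.gff3")
  spec_path <- file.path(out_dir, "spec.tsv")
  Biostrings::writeXStringSet(sequences, fasta_path)
  .write_sim_gff3(spec, gff3_path)
  utils::write.table(spec, spec_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta_path = fasta_path, gff3_path = gff3_path, spec_path = spec_path,
       spec = spec, sequences = sequences, config = config)
}

# GFF3 in transcript space: each transcript is its own reference sequence
.write_sim_gff3 <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(spec))) {
    tid <- spec$transcript_id[i]; gid <- spec$gene_id[i]
    len <- spec$length[i]
    cds_start <- spec$utr5_len[i] + 1L
    cds_end <- spec$utr5_len[i] + spec$cds_len[i]
    writeLines(c(
      sprintf("%s\triboprof_sim\tgene\t1\t%d\t.\t+\t.\tID=%s", tid, len, gid),
      sprintf("%s\triboprof_sim\tmRNA\t1\t%d\t.\t+\t.\tID=%s;Parent=%s",
              tid, len, tid, gid),
      sprintf("%s\triboprof_sim\texon\t1\t%d\t.\t+\t.\tID=%s.exon1;Parent=%s",
              tid, len, tid, tid),
      sprintf("%s\triboprof_sim\tCDS\t%d\t%d\t.\t+\t0\tID=%s.cds;Parent=%s",
              tid, cds_start, cds_end, tid, tid)
    ), con)
  }
  invisible(path)
}

#' Simulate a Ribo-seq library
#'
#' Draws footprints from a synthetic transcriptome with known ground
#' truth. Per read: the gene is drawn proportionally to
#' `abundance * loading * cds_len`; the true P-site codon is drawn within
#' the CDS (uniformly, or per `dwell_weights`); with probability
#' `periodicity_fidelity` the 5' end is placed exactly at
#' `p_site - psite_offset`, otherwise jittered by +/-1 nt; the fragment
#' length is drawn from `ribo_length_mix`. Reads that would overhang
#' either transcript end are redrawn (tallied in `n_redrawn`).
#'
#' Replicate libraries are made independent but reproducible by seeding
#' the generator with `config$seed + library_index`.
#'
#' @param config a [sim_config()].
#' @param transcriptome output of [simulate_transcriptome()].
#' @param sam_path optional path; when given, the library is also written
#'   as sense-strand SAM against the transcript reference.
#' @param library_index integer distinguishing replicate libraries
#'   (default 1).
#' @return list with `records` (footprint data.frame: `transcript_id`,
#'   `five_prime`, `length`), `truth` (adds `read_id`, `gene_id`,
#'   `true_p_site`), `sam_path` (or `NULL`) and `n_redrawn`.
#' @export
simulate_ribo <- function(config, transcriptome, sam_path = NULL,
                          library_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  spec <- transcriptome$spec
  n <- config$n_reads
  lengths_avail <- as.integer(names(config$ribo_length_mix))
  gene_w <- spec$abundance * spec$loading * spec$cds_len
  n_redrawn <- 0L
  withr::with_seed(config$seed + as.integer(library_index), {
    draw <- function(k) {
      gi <- sample.int(nrow(spec), k, replace = TRUE, prob = gene_w)
      n_codons <- spec$cds_len[gi] %/% 3L
      codon <- if (is.null(config$dwell_weights)) {
        floor(stats::runif(k) * n_codons)  # uniform over codons
      } else {
        vapply(n_codons, function(nc)
          sample.int(nc, 1L, prob = config$dwell_weights(nc)) - 1L, 1L)
      }
      p_site <- spec$utr5_len[gi] + 3L * codon
      u <- stats::runif(k)
      jitter <- ifelse(u < config$periodicity_fidelity, 0L,
                       ifelse(u < (1 + config$periodicity_fidelity) / 2, -1L, 1L))
      five_prime <- p_site - config$psite_offset + jitter
      len <- sample(lengths_avail, k, replace = TRUE,
                    prob = config$ribo_length_mix)
      data.frame(gi = gi, p_site = p_site, five_prime = five_prime,
                 length = len)
    }
    d <- draw(n)
    repeat {
      bad <- d$five_prime < 0L |
        d$five_prime + d$length > spec$length[d$gi]
      if (!any(bad)) break
      n_redrawn <- n_redrawn + sum(bad)
      d[bad, ] <- draw(sum(bad))
    }
  })
  truth <- data.frame(
    read_id = sprintf("ribo%d_%07d", as.integer(library_index), seq_len(n)),
    transcript_id = spec$transcript_id[d$gi],
    gene_id = spec$gene_id[d$gi],
    five_prime = d$five_prime,
    length = d$length,
    true_p_site = d$p_site,
    stringsAsFactors = FALSE
  )
  records <- truth[, c("transcript_id", "five_prime", "length")]
  if (!is.null(sam_path))
    .write_sam(truth, transcriptome, sam_path)
  list(records = records, truth = truth,
       sam_path = sam_path, n_redrawn = n_redrawn)
}

#' Simulate an RNA-seq library
#'
#' Total-RNA counterpart of [simulate_ribo()]: the gene is drawn
#' proportionally to `abundance * transcript_length`, the fragment 5' end
#' uniformly over all transcript positions, and the fragment length from
#' `rna_length_range` truncated at the 3' transcript end, so expected
#' region occupancy tracks region lengths exactly.
#'
#' @inheritParams simulate_ribo
#' @return list with `records`, `truth` (no P-site: `true_p_site` is
#'   `NA`), `sam_path` and `n_redrawn` (always 0 for RNA).
#' @export
simulate_rna <- function(config, transcriptome, sam_path = NULL,
                         library_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  spec <- transcriptome$spec
  n <- config$n_reads
  gene_w <- spec$abundance * spec$length
  withr::with_seed(config$seed + 1000L + as.integer(library_index), {
    gi <- sample.int(nrow(spec), n, replace = TRUE, prob = gene_w)
    five_prime <- floor(stats::runif(n) * spec$length[gi])
    len <- .sample_range(config$rna_length_range, n)
    len <- pmin(len, spec$length[gi] - five_prime)
  })
  truth <- data.frame(
    read_id = sprintf("rna%d_%07d", as.integer(library_index), seq_len(n)),
    transcript_id = spec$transcript_id[gi],
    gene_id = spec$gene_id[gi],
    five_prime = as.integer(five_prime),
    length = as.integer(len),
    true_p_site = NA_integer_,
    stringsAsFactors = FALSE
  )
  records <- truth[, c("transcript_id", "five_prime", "length")]
  if (!is.null(sam_path))
    .write_sam(truth, transcriptome, sam_path)
  list(records = records, truth = truth, sam_path = sam_path, n_redrawn = 0L)
}

# sense-strand SAM against the transcript reference; n_reads = 0 yields a
# valid header-only file
.write_sam <- function(truth, transcriptome, path) {
  spec <- transcriptome$spec
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", spec$transcript_id, spec$length))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(truth) > 0L) {
    seqs <- as.character(Biostrings::subseq(
      transcriptome$sequences[truth$transcript_id],
      start = truth$five_prime + 1L, width = truth$length))
    writeLines(sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                       truth$read_id, truth$transcript_id,
                       truth$five_prime + 1L, truth$length, seqs), con)
  }
  invisible(path)
}

#' Write simulated reads as FASTQ
#'
#' Convenience writer for end-to-end demonstrations with an external
#' aligner; the in-package pipeline consumes the simulator's SAM directly.
#'
#' @param truth truth table from [simulate_ribo()] or [simulate_rna()].
#' @param transcriptome output of [simulate_transcriptome()].
#' @param path output FASTQ path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(truth, transcriptome, path) {
  seqs <- as.character(Biostrings::subseq(
    transcriptome$sequences[truth$transcript_id],
    start = truth$five_prime + 1L, width = truth$length))
  quals <- vapply(truth$length, function(l)
    paste(rep("I", l), collapse = ""), character(1))
  writeLines(as.vector(rbind(paste0("@", truth$read_id), seqs, "+", quals)),
             path)
  invisible(path)
}
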