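# In-code fixtures shared across test files.

# Minimal TranscriptSet built directly (bypasses GFF3 parsing, which has
# its own tests) for unit tests of coordinate arithmetic.
toy_transcript_set <- function(utr5, cds, utr3, tid = "tx1", gid = "gene1",
                               cds_complete = (cds %% 3L) == 0L) {
  n <- length(utr5)
  tid <- rep_len(tid, n); gid <- rep_len(gid, n)
  models <- data.frame(
    transcript_id = tid, gene_id = gid,
    length = as.integer(utr5 + cds + utr3),
    utr5_len = as.integer(utr5), cds_len = as.integer(cds),
    utr3_len = as.integer(utr3),
    cds_complete = rep_len(cds_complete, n),
    stringsAsFactors = FALSE
  )
  rownames(models) <- models$transcript_id
  gene_index <- vapply(
    split(seq_len(n), models$gene_id),
    function(idx) representative_transcript(models[idx, , drop = FALSE]),
    character(1))
  structure(list(models = models, gene_index = gene_index, sequences = NULL),
            class = "TranscriptSet")
}

# Hand-written single-transcript GFF3 (transcript-space coordinates).
write_toy_gff3 <- function(path, tx_len = 300L, cds_start1 = 101L,
                           cds_end1 = 250L, tid = "txA", gid = "geneA") {
  writeLines(c(
    "##gff-version 3",
    sprintf("%s\ttest\tgene\t1\t%d\t.\t+\t.\tID=%s", tid, tx_len, gid),
    sprintf("%s\ttest\tmRNA\t1\t%d\t.\t+\t.\tID=%s;Parent=%s",
            tid, tx_len, tid, gid),
    sprintf("%s\ttest\texon\t1\t%d\t.\t+\t.\tID=%s.e1;Parent=%s",
            tid, tx_len, tid, tid),
    sprintf("%s\ttest\tCDS\t%d\t%d\t.\t+\t0\tID=%s.c;Parent=%s",
            tid, cds_start1, cds_end1, tid, tid)
  ), path)
  path
}

# Hand-written SAM against an arbitrary set of references.
# reads: data.frame(qname, flag, rname, pos1, cigar)
write_toy_sam <- function(path, refs, reads) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(refs), unname(refs)))
  if (nrow(reads) > 0L) {
    seq <- vapply(reads$cigar, function(cg) {
      n <- sum(as.integer(regmatches(cg, gregexpr("[0-9]+(?=[MIS=X])",
                                                  cg, perl = TRUE))[[1]]))
      paste(rep("A", n), collapse = "")
    }, character(1))
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
                              reads$qname, reads$flag, reads$rname,
                              reads$pos1, reads$cigar, seq))
  }
  writeLines(lines, path)
  path
}

# A small shared simulation, built once per test run.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 20L, n_reads = 10000L, seed = 101L)
      tx <- simulate_transcriptome(cfg, file.path(tempdir(), "shared_sim"))
      cache <<- list(config = cfg, tx = tx,
                     transcripts = load_transcripts(tx$gff3_path,
                                                    tx$fasta_path))
    }
    cache
  }
})
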