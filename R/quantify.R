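#' Count CDS-filtered reads per gene
#'
#' A footprint counts toward its gene when its A-site codon starts at
#' least `min_downstream` nt downstream of the first nucleotide of the
#' start codon (inclusive: a read whose A-site sits exactly 20 nt
#' downstream is counted) and lies within the CDS. The downstream filter
#' removes the initiation peak, whose occupancy reflects start-codon
#' kinetics rather than steady-state elongation.
#'
#' Genes are resolved through the `TranscriptSet` gene index; records on
#' transcripts other than a gene's representative are ignored.
#'
#' @param records site-annotated records from [assign_sites()].
#' @param transcripts a `TranscriptSet`.
#' @param min_downstream minimum A-site distance downstream of the start
#'   codon, in nt (default 20).
#' @return named integer vector of counts, one per gene in `transcripts`
#'   (zero for genes with no qualifying read).
#' @export
count_cds_reads <- function(records, transcripts, min_downstream = 20L) {
  rep_tx <- transcripts$gene_index
  m <- .models_for(transcripts, records$transcript_id)
  on_rep <- records$transcript_id %in% rep_tx
  downstream <- records$a_site - m$utr5_len
  a_in_cds <- !is.na(m$length) & records$a_site >= m$utr5_len &
    records$a_site < m$utr5_len + m$cds_len
  ok <- records$valid & on_rep & a_in_cds & downstream >= min_downstream
  counted <- table(factor(m$gene_id[ok], levels = names(rep_tx)))
  stats::setNames(as.integer(counted), names(rep_tx))
}

#' Reads per kilobase of CDS per million mapped reads
#'
#' `rpkm = count * 1e9 / (cds_len * library_size)`: the count normalised
#' by CDS length in kilobases and sequencing depth in millions.
#'
#' @param count read count(s).
#' @param cds_len CDS length(s) in nt; must be positive.
#' @param library_size total mapped reads used as the depth denominator;
#'   must be positive.
#' @return numeric RPKM value(s).
#' @examples
#' rpkm(1000, 2000, 1e7)  # 50
#' @export
rpkm <- function(count, cds_len, library_size) {
  if (any(cds_len <= 0)) stop("cds_len must be positive", call. = FALSE)
  if (any(library_size <= 0)) stop("library_size must be positive", call. = FALSE)
  count * 1e9 / (cds_len * library_size)
}

#' Gene-level expression table
#'
#' Combines [count_cds_reads()] with [rpkm()] into the per-gene
#' quantification used throughout: CDS-filtered counts, CDS lengths and
#' RPKM. The depth denominator defaults to the number of records supplied,
#' i.e. reads surviving ingestion and length filtering for a Ribo-seq
#' library (for RNA-seq pass all ingested records); it can be overridden
#' and is recorded in the result.
#'
#' @param records site-annotated records from [assign_sites()].
#' @param transcripts a `TranscriptSet`.
#' @param min_downstream A-site downstream filter in nt (default 20).
#' @param library_size depth denominator; default `nrow(records)`.
#' @return data.frame with columns `gene_id`, `cds_len`, `count`, `rpkm`;
#'   attributes `library_size`, `min_downstream`.
#' @export
gene_expression_table <- function(records, transcripts,
                                  min_downstream = 20L,
                                  library_size = nrow(records)) {
  counts <- count_cds_reads(records, transcripts, min_downstream)
  rep_models <- .models_for(transcripts, transcripts$gene_index)
  out <- data.frame(
    gene_id = names(counts),
    cds_len = rep_models$cds_len,
    count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  out$rpkm <- rpkm(out$count, out$cds_len, library_size)
  attr(out, "library_size") <- library_size
  attr(out, "min_downstream") <- min_downstream
  out
}

#' Translation efficiency per gene
#'
#' `TE = RPKM_ribo / RPKM_rna`: ribosome loading normalised by mRNA
#' abundance. Genes absent from either table, or with zero RNA-seq RPKM,
#' are omitted and tallied in the `n_omitted` attribute.
#'
#' @param ribo,rna gene expression tables from [gene_expression_table()].
#' @return data.frame with columns `gene_id`, `rpkm_ribo`, `rpkm_rna`,
#'   `te`; attribute `n_omitted`.
#' @export
translation_efficiency <- function(ribo, rna) {
  common <- intersect(ribo$gene_id, rna$gene_id)
  n_omitted <- length(union(ribo$gene_id, rna$gene_id)) - length(common)
  r1 <- ribo$rpkm[match(common, ribo$gene_id)]
  r2 <- rna$rpkm[match(common, rna$gene_id)]
  defined <- r2 > 0
  n_omitted <- n_omitted + sum(!defined)
  out <- data.frame(
    gene_id = common[defined],
    rpkm_ribo = r1[defined],
    rpkm_rna = r2[defined],
    te = r1[defined] / r2[defined],
    stringsAsFactors = FALSE
  )
  attr(out, "n_omitted") <- n_omitted
  out
}
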