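#' Build transcript coordinate models from GFF3 and FASTA
#'
#' Parses a GFF3 annotation (and optionally matching transcript sequences)
#' into a `TranscriptSet`: one coordinate model per transcript giving the
#' extents of the 5'UTR, CDS and 3'UTR in transcript space. All internal
#' coordinates are 0-based, half-open and transcript-relative; GFF3's
#' 1-based closed intervals are converted at this boundary.
#'
#' Transcripts are recognised as features of type `mRNA` or `transcript`
#' with an `ID` attribute; their `exon` and `CDS` children are projected
#' into transcript coordinates by cumulating exon widths along the
#' transcript strand. Transcripts without any CDS child are excluded (their
#' number is reported via a message). A CDS whose total length is not a
#' multiple of 3 is retained with `cds_complete = FALSE`; such models are
#' kept for length/region QC but excluded from frame analysis downstream.
#'
#' @param gff3_path path to a GFF3 file.
#' @param fasta_path optional path to a FASTA file of transcript sequences;
#'   ids must match transcript ids. Transcripts present in the GFF3 but
#'   absent from the FASTA (or with mismatching lengths) are dropped with a
#'   warning.
#' @return A `TranscriptSet`: a list with elements
#'   \describe{
#'     \item{models}{data.frame with columns `transcript_id`, `gene_id`,
#'       `length`, `utr5_len`, `cds_len`, `utr3_len`, `cds_complete`.}
#'     \item{gene_index}{named character vector mapping each `gene_id` to
#'       its representative transcript (longest CDS; see
#'       [representative_transcript()]).}
#'     \item{sequences}{`DNAStringSet` of transcript sequences, or `NULL`.}
#'   }
#' @examples
#' sim <- simulate_transcriptome(sim_config(n_genes = 3, seed = 1),
#'                               out_dir = tempfile("tx"))
#' txs <- load_transcripts(sim$gff3_path, sim$fasta_path)
#' txs$models
#' @export
load_transcripts <- function(gff3_path, fasta_path = NULL) {
  gff <- tryCatch(
    rtracklayer::import(gff3_path, format = "gff3"),
    error = function(e) stop("unparsable GFF3 '", gff3_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  type <- as.character(gff$type)
  tx_feats <- gff[type %in% c("mRNA", "transcript")]
  if (length(tx_feats) == 0L)
    stop("GFF3 contains no mRNA/transcript features", call. = FALSE)
  tx_ids <- as.character(tx_feats$ID)
  gene_ids <- .first_parent(tx_feats)
  gene_ids[is.na(gene_ids)] <- tx_ids[is.na(gene_ids)]

  child_parent <- .first_parent(gff)
  exons <- gff[type == "exon"]
  cdss  <- gff[type == "CDS"]
  exon_parent <- .first_parent(exons)
  cds_parent  <- .first_parent(cdss)

  rows <- vector("list", length(tx_ids))
  n_no_cds <- 0L
  for (i in seq_along(tx_ids)) {
    tid <- tx_ids[[i]]
    ex <- exons[!is.na(exon_parent) & exon_parent == tid]
    cd <- cdss[!is.na(cds_parent) & cds_parent == tid]
    if (length(ex) == 0L) {
      # single-block transcript: the feature itself is the exon
      ex <- tx_feats[i]
    }
    if (length(cd) == 0L) {
      n_no_cds <- n_no_cds + 1L
      next
    }
    strand <- as.character(GenomicRanges::strand(ex))[1]
    ord <- order(GenomicRanges::start(ex),
                 decreasing = identical(strand, "-"))
    ex <- ex[ord]
    widths <- GenomicRanges::width(ex)
    tx_len <- sum(widths)
    # transcript coordinate of each exon's 5'-most genomic base
    offsets <- cumsum(c(0L, widths[-length(widths)]))
    cds_len <- sum(GenomicRanges::width(cd))
    # genomic position of the CDS 5' end (strand-aware)
    cds_start_genomic <- if (identical(strand, "-"))
      max(GenomicRanges::end(cd)) else min(GenomicRanges::start(cd))
    utr5 <- NA_integer_
    for (j in seq_along(ex)) {
      s <- GenomicRanges::start(ex)[j]; e <- GenomicRanges::end(ex)[j]
      if (cds_start_genomic >= s && cds_start_genomic <= e) {
        within <- if (identical(strand, "-")) e - cds_start_genomic
                  else cds_start_genomic - s
        utr5 <- offsets[j] + within
        break
      }
    }
    if (is.na(utr5)) {
      warning("CDS of transcript '", tid, "' does not fall within its exons; dropped")
      next
    }
    rows[[i]] <- data.frame(
      transcript_id = tid,
      gene_id = gene_ids[[i]],
      length = as.integer(tx_len),
      utr5_len = as.integer(utr5),
      cds_len = as.integer(cds_len),
      utr3_len = as.integer(tx_len - utr5 - cds_len),
      cds_complete = (cds_len %% 3L) == 0L,
      stringsAsFactors = FALSE
    )
  }
  models <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(models) || nrow(models) == 0L)
    stop("no transcript with an annotated CDS found", call. = FALSE)
  if (n_no_cds > 0L)
    message(n_no_cds, " transcript(s) without CDS excluded")
  bad <- models$utr3_len < 0L
  if (any(bad)) {
    warning(sum(bad), " transcript(s) with CDS exceeding exonic extent dropped")
    models <- models[!bad, , drop = FALSE]
  }

  sequences <- NULL
  if (!is.null(fasta_path)) {
    sequences <- Biostrings::readDNAStringSet(fasta_path)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
    missing <- setdiff(models$transcript_id, names(sequences))
    if (length(missing) > 0L) {
      warning(length(missing), " transcript(s) missing from FASTA dropped: ",
              paste(utils::head(missing, 5), collapse = ", "))
      models <- models[!models$transcript_id %in% missing, , drop = FALSE]
    }
    seq_len_mismatch <- models$transcript_id[
      Biostrings::width(sequences[models$transcript_id]) != models$length]
    if (length(seq_len_mismatch) > 0L) {
      warning(length(seq_len_mismatch),
              " transcript(s) with FASTA/GFF3 length mismatch dropped")
      models <- models[!models$transcript_id %in% seq_len_mismatch, , drop = FALSE]
    }
    if (nrow(models) == 0L)
      stop("no transcript left after FASTA/GFF3 reconciliation", call. = FALSE)
    sequences <- sequences[models$transcript_id]
  }
  rownames(models) <- models$transcript_id
  gene_index <- vapply(
    split(seq_len(nrow(models)), models$gene_id),
    function(idx) representative_transcript(models[idx, , drop = FALSE]),
    character(1)
  )
  structure(
    list(models = models, gene_index = gene_index, sequences = sequences),
    class = "TranscriptSet"
  )
}

# first Parent attribute of each feature, NA when absent
.first_parent <- function(gr) {
  p <- gr$Parent
  if (is.null(p)) return(rep(NA_character_, length(gr)))
  vapply(as.list(p), function(x) if (length(x)) as.character(x[[1]]) else NA_character_,
         character(1))
}

#' @export
print.TranscriptSet <- function(x, ...) {
  cat("TranscriptSet with", nrow(x$models), "transcripts /",
      length(x$gene_index), "genes\n")
  cat("  sequences:", if (is.null(x$sequences)) "absent" else "present", "\n")
  cat("  incomplete CDS:", sum(!x$models$cds_complete), "\n")
  invisible(x)
}

#' Region of a transcript position
#'
#' Classifies a 0-based transcript position as `UTR5`, `CDS` or `UTR3`
#' under the model's half-open region partition: `UTR5` covers
#' `[0, utr5_len)`, `CDS` covers `[utr5_len, utr5_len + cds_len)`, and
#' `UTR3` the remainder.
#'
#' @param model a single-row model data.frame (one row of
#'   `TranscriptSet$models`) or a list with `utr5_len`, `cds_len`, `length`.
#' @param pos 0-based position(s); vectorised.
#' @return character vector in `{"UTR5","CDS","UTR3"}`.
#' @export
region_of <- function(model, pos) {
  if (any(pos < 0L | pos >= model$length))
    stop("position out of range [0, ", model$length, ")", call. = FALSE)
  cds_start <- model$utr5_len
  cds_end <- model$utr5_len + model$cds_len
  ifelse(pos < cds_start, "UTR5", ifelse(pos < cds_end, "CDS", "UTR3"))
}

#' Choose a gene's representative transcript
#'
#' Deterministic policy used to collapse multi-isoform genes to a single
#' transcript for quantification: longest CDS, ties broken by longest
#' transcript, then lexicographically smallest id.
#'
#' @param models_for_gene data.frame of models sharing one `gene_id`.
#' @return the chosen `transcript_id`.
#' @export
representative_transcript <- function(models_for_gene) {
  if (nrow(models_for_gene) == 0L)
    stop("empty model collection", call. = FALSE)
  ord <- order(-models_for_gene$cds_len, -models_for_gene$length,
               models_for_gene$transcript_id)
  models_for_gene$transcript_id[ord[1]]
}

# fast lookup of model rows for a vector of transcript ids (NA row when absent)
.models_for <- function(transcripts, transcript_id) {
  transcripts$models[match(transcript_id, transcripts$models$transcript_id), ,
                     drop = FALSE]
}
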