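#' Assign P-site, A-site, frame and region to footprints
#'
#' Places the ribosomal P-site a fixed number of nucleotides downstream of
#' each footprint's 5' end (12 nt by default, applied to all fragment
#' lengths) and the A-site one codon (3 nt) further 3'. The reading frame
#' is defined only when the P-site falls inside the CDS, as
#' `(p_site - utr5_len) mod 3`; frame 0 marks P-sites in phase with the
#' start codon. Records whose P-site or A-site falls outside the
#' transcript, or that reference an unknown transcript, are flagged
#' `valid = FALSE` and tallied rather than dropped, so callers can report
#' them.
#'
#' An optional per-length offset table is accepted for generality: a named
#' numeric vector mapping fragment length to offset, consulted before
#' falling back to the scalar `offset`.
#'
#' @param records footprint record data.frame from [read_alignments()].
#' @param transcripts a `TranscriptSet`.
#' @param offset 5'-end to P-site offset in nt (default 12).
#' @param offset_by_length optional named vector, e.g.
#'   `c("21" = 12, "28" = 12)`.
#' @return data.frame extending `records` with columns `p_site`, `a_site`,
#'   `frame` (integer 0/1/2 or `NA`), `region` (`UTR5`/`CDS`/`UTR3` or
#'   `NA`), `valid`; attribute `n_invalid` counts flagged records. Frames
#'   are additionally `NA` on transcripts whose CDS length is not a
#'   multiple of 3.
#' @examples
#' recs <- data.frame(transcript_id = "tx1", five_prime = 88L, length = 28L)
#' @export
assign_sites <- function(records, transcripts, offset = 12L,
                         offset_by_length = NULL) {
  stopifnot(offset >= 0L)
  off <- rep(as.integer(offset), nrow(records))
  if (!is.null(offset_by_length)) {
    hit <- match(as.character(records$length), names(offset_by_length))
    off[!is.na(hit)] <- as.integer(offset_by_length[hit[!is.na(hit)]])
  }
  m <- .models_for(transcripts, records$transcript_id)
  p_site <- records$five_prime + off
  a_site <- p_site + 3L
  known <- !is.na(m$length)
  valid <- known & p_site >= 0L & a_site + 2L < m$length
  cds_start <- m$utr5_len
  cds_end <- m$utr5_len + m$cds_len
  region <- ifelse(!valid, NA_character_,
            ifelse(p_site < cds_start, "UTR5",
            ifelse(p_site < cds_end, "CDS", "UTR3")))
  in_cds <- valid & region == "CDS" & m$cds_complete
  frame <- ifelse(in_cds, (p_site - cds_start) %% 3L, NA_integer_)
  out <- records
  out$p_site <- p_site
  out$a_site <- a_site
  out$frame <- as.integer(frame)
  out$region <- region
  out$valid <- valid
  attr(out, "n_invalid") <- sum(!valid)
  out
}

#' Reading frame of a P-site position
#'
#' @param p_site 0-based transcript position(s).
#' @param model single-row transcript model.
#' @return integer 0/1/2 when the P-site lies in the CDS, `NA` otherwise.
#' @export
frame_of <- function(p_site, model) {
  in_cds <- p_site >= model$utr5_len & p_site < model$utr5_len + model$cds_len
  ifelse(in_cds, (p_site - model$utr5_len) %% 3L, NA_integer_)
}
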