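#' Read-region distribution over 5'UTR / CDS / 3'UTR
#'
#' The second standard Ribo-seq validation view: footprints should fall
#' overwhelmingly inside coding sequences, whereas RNA-seq reads distribute
#' roughly in proportion to region lengths (in a typical transcriptome
#' about 60% of RNA-seq reads land in the CDS simply because CDSs are
#' longer than UTRs).
#'
#' The anchoring position differs by assay: ribosome footprints are
#' assigned by their P-site (`mode = "psite"`; `records` must come from
#' [assign_sites()], and invalid records are ignored), RNA-seq reads by
#' their 5' end (`mode = "five_prime"`). Records on unknown transcripts
#' are skipped and tallied.
#'
#' @param records footprint records (site-annotated for `mode = "psite"`).
#' @param transcripts a `TranscriptSet`.
#' @param mode `"psite"` or `"five_prime"`.
#' @return data.frame with rows `UTR5`, `CDS`, `UTR3` and columns `region`,
#'   `count`, `fraction`; attributes `n_used`, `n_skipped`. With no usable
#'   records counts are zero and fractions `NA`.
#' @export
region_distribution <- function(records, transcripts,
                                mode = c("psite", "five_prime")) {
  mode <- match.arg(mode)
  if (mode == "psite") {
    if (is.null(records$region))
      stop("mode='psite' needs site-annotated records (assign_sites)",
           call. = FALSE)
    region <- records$region[records$valid]
    n_skipped <- sum(!records$valid)
  } else {
    m <- .models_for(transcripts, records$transcript_id)
    known <- !is.na(m$length)
    pos <- records$five_prime[known]
    mk <- m[known, , drop = FALSE]
    region <- ifelse(pos < mk$utr5_len, "UTR5",
              ifelse(pos < mk$utr5_len + mk$cds_len, "CDS", "UTR3"))
    n_skipped <- sum(!known)
  }
  lev <- c("UTR5", "CDS", "UTR3")
  counts <- as.integer(table(factor(region, levels = lev)))
  total <- sum(counts)
  out <- data.frame(region = lev, count = counts,
                    fraction = if (total > 0) counts / total else NA_real_)
  attr(out, "n_used") <- total
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Metagene profile of footprint 5' ends around the start codon
#'
#' Aggregates, over all transcripts, the positions of footprint 5' ends
#' relative to the first nucleotide of the start codon (position 0),
#' separately for each fragment-length class. With a fixed 5'-end P-site
#' offset of 12 nt, initiating ribosomes (start codon in the P-site)
#' produce a peak at position -12; the 3-nt phasing of the profile within
#' the CDS is the triplet periodicity diagnostic of genuine translation.
#'
#' @param records footprint record data.frame.
#' @param transcripts a `TranscriptSet`.
#' @param window integer `c(lo, hi)` with `lo < 0 < hi`; default
#'   `c(-40, 60)`.
#' @param length_classes a `length_windows` object defining the classes;
#'   default [rpf_windows()]. Records outside every class are ignored. An
#'   empty window set pools all lengths into one class `"all"`.
#' @return data.frame with columns `length_class`, `position` (every
#'   integer in `[lo, hi]` for every class), `count`, `fraction`
#'   (normalised within class; `NA` for empty classes).
#' @export
metagene_start_profile <- function(records, transcripts,
                                   window = c(-40L, 60L),
                                   length_classes = rpf_windows()) {
  stopifnot(length(window) == 2L, window[1] < 0L, window[2] > 0L)
  m <- .models_for(transcripts, records$transcript_id)
  rel <- records$five_prime - m$utr5_len
  if (nrow(length_classes) == 0L) {
    cls <- rep("all", nrow(records))
    class_levels <- "all"
  } else {
    cls <- .window_class(records$length, length_classes)
    class_levels <- paste0(length_classes$lo, "-", length_classes$hi)
  }
  ok <- !is.na(m$length) & !is.na(cls) &
    rel >= window[1] & rel <= window[2]
  positions <- seq.int(window[1], window[2])
  tab <- table(factor(cls[ok], levels = class_levels),
               factor(rel[ok], levels = positions))
  out <- data.frame(
    length_class = rep(class_levels, each = length(positions)),
    position = rep(positions, times = length(class_levels)),
    count = as.integer(t(tab))
  )
  tot <- stats::ave(out$count, out$length_class, FUN = sum)
  out$fraction <- ifelse(tot > 0, out$count / tot, NA_real_)
  out
}

#' Reading-frame distribution per length class
#'
#' Fraction of P-sites in each of the three codon positions, per
#' fragment-length class. Footprints from translating ribosomes phase
#' strongly into frame 0; RNA-seq reads processed identically split
#' roughly evenly across frames.
#'
#' @param records site-annotated records from [assign_sites()]; only
#'   records with a defined frame (P-site in a complete CDS) contribute.
#' @param length_classes a `length_windows`; empty set pools all lengths
#'   into class `"all"`.
#' @return data.frame with columns `length_class`, `frame` (0/1/2),
#'   `count`, `fraction` (within class; `NA` for empty classes).
#' @export
frame_distribution <- function(records, length_classes = rpf_windows()) {
  if (nrow(length_classes) == 0L) {
    cls <- rep("all", nrow(records))
    class_levels <- "all"
  } else {
    cls <- .window_class(records$length, length_classes)
    class_levels <- paste0(length_classes$lo, "-", length_classes$hi)
  }
  ok <- !is.na(records$frame) & !is.na(cls)
  tab <- table(factor(cls[ok], levels = class_levels),
               factor(records$frame[ok], levels = 0:2))
  out <- data.frame(
    length_class = rep(class_levels, each = 3L),
    frame = rep(0:2, times = length(class_levels)),
    count = as.integer(t(tab))
  )
  tot <- stats::ave(out$count, out$length_class, FUN = sum)
  out$fraction <- ifelse(tot > 0, out$count / tot, NA_real_)
  out
}

#' Periodicity score
#'
#' Summarises a frame distribution as the maximum frame fraction per
#' length class: 1/3 for frame-uniform (RNA-like) data, approaching 1 for
#' perfectly phased ribosome footprints.
#'
#' @param fd output of [frame_distribution()].
#' @return data.frame with columns `length_class`, `score` (`NA` for
#'   classes with no framed records).
#' @export
periodicity_score <- function(fd) {
  agg <- stats::aggregate(fraction ~ length_class, data = fd,
                          FUN = max, na.action = NULL)
  names(agg)[2] <- "score"
  agg[match(unique(fd$length_class), agg$length_class), , drop = FALSE]
}
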