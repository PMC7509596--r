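#' Length windows for footprint filtering
#'
#' Ribosome-protected fragments concentrate in two length modes
#' (20–22 nt and 27–29 nt); downstream analyses restrict to those windows.
#'
#' @param spec either a character like `"20-22,27-29"`, a list of
#'   `c(lo, hi)` integer pairs, or a two-column matrix/data.frame.
#' @return a `length_windows` object: data.frame with columns `lo`, `hi`.
#' @examples
#' rpf_windows()              # the default 20-22,27-29
#' length_windows("25-34")
#' @export
length_windows <- function(spec) {
  if (is.character(spec)) {
    parts <- strsplit(strsplit(spec, ",")[[1]], "-")
    df <- data.frame(lo = as.integer(vapply(parts, `[`, "", 1)),
                     hi = as.integer(vapply(parts, `[`, "", 2)))
  } else if (is.list(spec) && !is.data.frame(spec)) {
    df <- data.frame(lo = vapply(spec, function(w) as.integer(w[1]), 1L),
                     hi = vapply(spec, function(w) as.integer(w[2]), 1L))
  } else {
    df <- as.data.frame(spec)
    names(df) <- c("lo", "hi")
  }
  if (nrow(df) > 0) {
    stopifnot(all(df$lo <= df$hi))
    df <- df[order(df$lo), , drop = FALSE]
    if (nrow(df) > 1 && any(df$lo[-1] <= df$hi[-nrow(df)]))
      stop("length windows overlap", call. = FALSE)
  }
  class(df) <- c("length_windows", "data.frame")
  df
}

#' @rdname length_windows
#' @export
rpf_windows <- function() length_windows("20-22,27-29")

# membership of integer lengths in any window
.in_windows <- function(len, windows) {
  if (nrow(windows) == 0L) return(rep(TRUE, length(len)))
  keep <- rep(FALSE, length(len))
  for (i in seq_len(nrow(windows)))
    keep <- keep | (len >= windows$lo[i] & len <= windows$hi[i])
  keep
}

# label of the window containing each length, NA if none
.window_class <- function(len, windows) {
  lab <- rep(NA_character_, length(len))
  for (i in seq_len(nrow(windows))) {
    sel <- len >= windows$lo[i] & len <= windows$hi[i]
    lab[sel] <- paste0(windows$lo[i], "-", windows$hi[i])
  }
  lab
}

#' Read transcriptome alignments into footprint records
#'
#' Streams primary, mapped, forward-strand alignments from a SAM or BAM
#' file aligned against a transcriptome reference and reduces each to a
#' footprint record: `(transcript_id, five_prime, length)`. `five_prime`
#' is the 0-based transcript coordinate of the leftmost aligned base
#' (reads are expected sense-strand on transcripts); `length` is the
#' aligned query span with soft-clipped bases excluded.
#'
#' Unmapped, secondary, supplementary and reverse-strand records, and
#' records whose reference is absent from `transcripts`, are skipped; the
#' tallies are returned in the `skipped` attribute and reported via a
#' message.
#'
#' @param sam_path path to a SAM or BAM file (SAM is converted on the fly).
#' @param transcripts a `TranscriptSet` from [load_transcripts()].
#' @return data.frame with columns `transcript_id`, `five_prime`, `length`,
#'   with attribute `skipped` (named integer vector of skip tallies).
#' @export
read_alignments <- function(sam_path, transcripts) {
  if (!file.exists(sam_path))
    stop("no such file: ", sam_path, call. = FALSE)
  bam_path <- sam_path
  if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    bam_path <- Rsamtools::asBam(sam_path, tempfile("aln"),
                                 indexDestination = FALSE, overwrite = TRUE)
  }
  res <- Rsamtools::scanBam(
    Rsamtools::BamFile(bam_path),
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar"))
  )[[1]]
  flag <- res$flag
  n <- length(flag)
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- !unmapped & bitwAnd(flag, 256L) != 0L
  supplementary <- !unmapped & !secondary & bitwAnd(flag, 2048L) != 0L
  reverse <- !unmapped & !secondary & !supplementary & bitwAnd(flag, 16L) != 0L
  keep <- !(unmapped | secondary | supplementary | reverse)
  rname <- as.character(res$rname)
  unknown <- keep & !(rname %in% transcripts$models$transcript_id)
  keep <- keep & !unknown
  skipped <- c(unmapped = sum(unmapped), secondary = sum(secondary),
               supplementary = sum(supplementary), reverse_strand = sum(reverse),
               unknown_reference = sum(unknown))
  if (any(skipped > 0L))
    message("read_alignments: skipped ",
            paste(names(skipped)[skipped > 0], skipped[skipped > 0],
                  sep = "=", collapse = ", "))
  if (sum(skipped) > 0L && sum(unknown) > 0L)
    warning(sum(unknown), " record(s) referenced transcripts absent from the annotation")
  len <- GenomicAlignments::cigarWidthAlongQuerySpace(
    res$cigar[keep], after.soft.clipping = TRUE)
  out <- data.frame(
    transcript_id = rname[keep],
    five_prime = res$pos[keep] - 1L,
    length = as.integer(len),
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- skipped
  out
}

#' Filter footprint records by fragment length
#'
#' Keeps records whose `length` falls inside any of the supplied inclusive
#' windows, preserving input order. An empty window set disables filtering
#' (all records kept).
#'
#' @param records footprint record data.frame.
#' @param windows a `length_windows` object; default [rpf_windows()].
#' @return the filtered data.frame.
#' @export
filter_by_length <- function(records, windows = rpf_windows()) {
  records[.in_windows(records$length, windows), , drop = FALSE]
}

#' Fragment-length histogram
#'
#' Counts records per exact fragment length, the first Ribo-seq validation
#' view: genuine ribosome-protected fragments concentrate in narrow length
#' modes while RNA-seq fragments spread more evenly.
#'
#' @param records footprint record data.frame.
#' @return data.frame with columns `length`, `count`, `fraction`, plus
#'   attribute `total`.
#' @export
length_histogram <- function(records) {
  if (nrow(records) == 0L) {
    out <- data.frame(length = integer(0), count = integer(0),
                      fraction = numeric(0))
    attr(out, "total") <- 0L
    return(out)
  }
  tab <- table(records$length)
  out <- data.frame(length = as.integer(names(tab)),
                    count = as.integer(tab))
  out$fraction <- out$count / sum(out$count)
  attr(out, "total") <- sum(out$count)
  out
}
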