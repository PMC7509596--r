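test_that("SAM records convert to 0-based footprint records", {
  ts <- toy_transcript_set(100L, 150L, 50L, tid = "txA", gid = "geneA")
  sam <- write_toy_sam(
    tempfile(fileext = ".sam"), c(txA = 300L),
    data.frame(qname = "r1", flag = 0L, rname = "txA", pos1 = 101L,
               cigar = "28M", stringsAsFactors = FALSE))
  rec <- read_alignments(sam, ts)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$five_prime, 100L)
  expect_equal(rec$length, 28L)
})

test_that("unmapped/secondary/reverse/unknown-reference records are skipped and tallied", {
  ts <- toy_transcript_set(100L, 150L, 50L, tid = "txA", gid = "geneA")
  reads <- data.frame(
    qname = c("ok", "unmapped", "rev", "sec"),
    flag = c(0L, 4L, 16L, 256L),
    rname = c("txA", "*", "txA", "txA"),
    pos1 = c(1L, 0L, 10L, 10L),
    cigar = c("28M", "*", "28M", "28M"),
    stringsAsFactors = FALSE)
  sam <- write_toy_sam(tempfile(fileext = ".sam"), c(txA = 300L, txB = 300L),
                       reads)
  expect_message(rec <- read_alignments(sam, ts), "skipped")
  expect_equal(rec$qname, NULL)
  expect_equal(nrow(rec), 1L)
  sk <- attr(rec, "skipped")
  expect_equal(unname(sk[c("unmapped", "reverse_strand", "secondary")]),
               c(1L, 1L, 1L))

  # unknown reference: aligned to txB which is absent from the annotation
  sam2 <- write_toy_sam(
    tempfile(fileext = ".sam"), c(txA = 300L, txB = 300L),
    data.frame(qname = "r", flag = 0L, rname = "txB", pos1 = 1L,
               cigar = "28M", stringsAsFactors = FALSE))
  expect_warning(rec2 <- read_alignments(sam2, ts), "absent from the annotation")
  expect_equal(nrow(rec2), 0L)
  expect_equal(unname(attr(rec2, "skipped")["unknown_reference"]), 1L)
})

test_that("soft-clipped bases are excluded from fragment length", {
  ts <- toy_transcript_set(100L, 150L, 50L, tid = "txA", gid = "geneA")
  sam <- write_toy_sam(
    tempfile(fileext = ".sam"), c(txA = 300L),
    data.frame(qname = "r1", flag = 0L, rname = "txA", pos1 = 51L,
               cigar = "2S26M3S", stringsAsFactors = FALSE))
  rec <- read_alignments(sam, ts)
  expect_equal(rec$length, 26L)
  expect_equal(rec$five_prime, 50L)
})

test_that("length filtering keeps the RPF windows and is idempotent", {
  rec <- data.frame(transcript_id = "t", five_prime = 0L,
                    length = c(19L, 20L, 21L, 22L, 25L, 27L, 29L, 30L))
  kept <- filter_by_length(rec, rpf_windows())
  expect_equal(kept$length, c(20L, 21L, 22L, 27L, 29L))
  expect_equal(filter_by_length(kept, rpf_windows()), kept)
  # empty window list disables filtering
  expect_equal(filter_by_length(rec, length_windows(list())), rec)
  # filtering commutes with the histogram restricted to window lengths
  h_then_f <- length_histogram(kept)
  h_all <- length_histogram(rec)
  expect_equal(h_then_f$count,
               h_all$count[h_all$length %in% kept$length])
})

test_that("length windows parse and reject overlaps", {
  w <- length_windows("20-22,27-29")
  expect_equal(w$lo, c(20L, 27L))
  expect_equal(w$hi, c(22L, 29L))
  expect_error(length_windows("20-25,24-29"), "overlap")
  expect_error(length_windows(list(c(22, 20))))
})

test_that("length histogram counts exact lengths", {
  rec <- data.frame(transcript_id = "t", five_prime = 0L,
                    length = c(28L, 28L, 21L))
  h <- length_histogram(rec)
  expect_equal(h$length, c(21L, 28L))
  expect_equal(h$count, c(1L, 2L))
  expect_equal(attr(h, "total"), 3L)
  h0 <- length_histogram(rec[0, ])
  expect_equal(nrow(h0), 0L)
  expect_equal(attr(h0, "total"), 0L)
})

test_that("simulated length mixture reproduces configured window masses", {
  s <- shared_sim()
  rb <- simulate_ribo(s$config, s$tx)
  h <- length_histogram(rb$records)
  mass_small <- sum(h$fraction[h$length >= 20 & h$length <= 22])
  mass_large <- sum(h$fraction[h$length >= 27 & h$length <= 29])
  expect_equal(mass_small, 0.4, tolerance = 0.02 / 0.4)
  expect_equal(mass_large, 0.6, tolerance = 0.02 / 0.6)
  expect_equal(mass_small + mass_large, 1)
})

test_that("simulated SAM yields exactly n records with no invariant violations", {
  s <- shared_sim()
  sam <- tempfile(fileext = ".sam")
  rb <- simulate_ribo(s$config, s$tx, sam_path = sam)
  rec <- read_alignments(sam, s$transcripts)
  expect_equal(nrow(rec), s$config$n_reads)
  expect_equal(sum(attr(rec, "skipped")), 0L)
  m <- s$transcripts$models[rec$transcript_id, ]
  expect_true(all(rec$five_prime >= 0L))
  expect_true(all(rec$five_prime < m$length))
  expect_true(all(rec$length >= 1L))
  expect_true(all(rec$five_prime + rec$length <= m$length))
})
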