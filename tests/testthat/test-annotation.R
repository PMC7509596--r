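test_that("GFF3 transcript models get correct UTR/CDS extents", {
  gff <- write_toy_gff3(tempfile(fileext = ".gff3"),
                        tx_len = 300L, cds_start1 = 101L, cds_end1 = 250L)
  ts <- load_transcripts(gff)
  m <- ts$models
  expect_equal(nrow(m), 1L)
  expect_equal(m$utr5_len, 100L)
  expect_equal(m$cds_len, 150L)
  expect_equal(m$utr3_len, 50L)
  expect_equal(m$length, 300L)
  expect_true(m$cds_complete)
})

test_that("CDS spanning the whole transcript yields zero-length UTRs", {
  gff <- write_toy_gff3(tempfile(fileext = ".gff3"),
                        tx_len = 300L, cds_start1 = 1L, cds_end1 = 300L)
  m <- load_transcripts(gff)$models
  expect_equal(m$utr5_len, 0L)
  expect_equal(m$utr3_len, 0L)
  expect_equal(m$cds_len, 300L)
})

test_that("multi-exon minus-strand CDS projects into transcript coordinates", {
  # two 100-nt exons on the minus strand; CDS spans the junction
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tmRNA\t101\t400\t.\t-\t.\tID=txM;Parent=geneM",
    "chr1\ttest\texon\t101\t200\t.\t-\t.\tID=txM.e2;Parent=txM",
    "chr1\ttest\texon\t301\t400\t.\t-\t.\tID=txM.e1;Parent=txM",
    "chr1\ttest\tCDS\t301\t380\t.\t-\t0\tID=txM.c1;Parent=txM",
    "chr1\ttest\tCDS\t151\t200\t.\t-\t2\tID=txM.c2;Parent=txM"
  ), gff)
  m <- load_transcripts(gff)$models
  expect_equal(m$length, 200L)
  expect_equal(m$utr5_len, 20L)   # 400 - 380 on the 5'-most exon
  expect_equal(m$cds_len, 130L)   # 80 + 50
  expect_equal(m$utr3_len, 50L)
  expect_false(m$cds_complete)    # 130 %% 3 != 0, downgraded not dropped
})

test_that("transcripts without CDS are excluded with a message", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "txA\ttest\tmRNA\t1\t300\t.\t+\t.\tID=txA;Parent=geneA",
    "txA\ttest\texon\t1\t300\t.\t+\t.\tID=txA.e;Parent=txA",
    "txA\ttest\tCDS\t101\t250\t.\t+\t0\tID=txA.c;Parent=txA",
    "txB\ttest\tmRNA\t1\t200\t.\t+\t.\tID=txB;Parent=geneB",
    "txB\ttest\texon\t1\t200\t.\t+\t.\tID=txB.e;Parent=txB"
  ), gff)
  expect_message(ts <- load_transcripts(gff), "without CDS")
  expect_equal(ts$models$transcript_id, "txA")
})

test_that("FASTA/GFF id mismatches are reported and transcripts dropped", {
  gff <- write_toy_gff3(tempfile(fileext = ".gff3"), tid = "txA")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">txOther", paste(rep("A", 300), collapse = "")), fa)
  expect_warning(expect_error(load_transcripts(gff, fa)), "missing from FASTA")
})

test_that("region_of partitions [0, length) with half-open boundaries", {
  ts <- toy_transcript_set(100L, 150L, 50L)
  m <- ts$models[1, ]
  expect_equal(region_of(m, 99L), "UTR5")
  expect_equal(region_of(m, 100L), "CDS")
  expect_equal(region_of(m, 249L), "CDS")
  expect_equal(region_of(m, 250L), "UTR3")
  expect_error(region_of(m, 300L), "out of range")
  expect_error(region_of(m, -1L), "out of range")
  # full partition: sizes of the three contiguous intervals sum to length
  r <- region_of(m, 0:(m$length - 1L))
  expect_equal(as.integer(table(factor(r, c("UTR5", "CDS", "UTR3")))),
               c(100L, 150L, 50L))
  expect_false(is.unsorted(match(r, c("UTR5", "CDS", "UTR3"))))
})

test_that("representative transcript follows longest-CDS with tie-breaks", {
  one <- toy_transcript_set(10L, 30L, 10L)
  expect_equal(representative_transcript(one$models), "tx1")
  two <- toy_transcript_set(c(10L, 10L), c(300L, 450L), c(10L, 10L),
                            tid = c("a", "b"))
  expect_equal(representative_transcript(two$models), "b")
  tie <- toy_transcript_set(c(100L, 200L), c(300L, 300L), c(100L, 100L),
                            tid = c("a", "b"))  # lengths 500 vs 600
  expect_equal(representative_transcript(tie$models), "b")
  lex <- toy_transcript_set(c(10L, 10L), c(30L, 30L), c(10L, 10L),
                            tid = c("zz", "aa"))
  expect_equal(representative_transcript(lex$models), "aa")
  expect_error(representative_transcript(one$models[0, ]), "empty")
})

test_that("simulator-emitted annotation round-trips exactly", {
  s <- shared_sim()
  m <- s$transcripts$models
  spec <- s$tx$spec
  expect_equal(m[spec$transcript_id, c("utr5_len", "cds_len", "utr3_len",
                                       "length")],
               spec[, c("utr5_len", "cds_len", "utr3_len", "length")],
               ignore_attr = TRUE)
  expect_equal(unname(s$transcripts$gene_index[spec$gene_id]),
               spec$transcript_id)
  expect_true(all(m$cds_complete))
})
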