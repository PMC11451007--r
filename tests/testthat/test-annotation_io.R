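test_that("region parsing and interval lengths follow 1-based inclusive arithmetic", {
  r <- parse_region("chr16:28,474,111-28,495,575:-")
  expect_equal(r$chrom, "chr16")
  expect_equal(r$strand, "-")
  expect_equal(interval_length(r), 28495575L - 28474111L + 1L)
  expect_equal(interval_length(tibble::tibble(start = 5, end = 5)), 1L)
  # independent oracle: length of the enumerated base set
  set.seed(1)
  for (k in 1:20) {
    a <- sample.int(1e6, 1); b <- a + sample.int(500, 1) - 1L
    expect_equal(interval_length(tibble::tibble(start = a, end = b)),
                 length(seq.int(a, b)))
  }
  expect_error(parse_region("chr1:banana"), "cannot parse")
})

test_that("GTF reading orders minus-strand exon chains 5' to 3'", {
  gtf <- c(
    'chrT\tx\ttranscript\t100\t399\t.\t-\t.\tgene_id "G"; transcript_id "t1";',
    'chrT\tx\texon\t100\t199\t.\t-\t.\tgene_id "G"; transcript_id "t1";',
    'chrT\tx\texon\t300\t399\t.\t-\t.\tgene_id "G"; transcript_id "t1";')
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  ts <- read_gtf(f, dialect = "caller", sample_id = "s1")
  ch <- exon_chain(ts, "s1", "t1")
  expect_equal(ch$start, c(300, 100))  # downstream-in-genome exon is 5'-most
  expect_equal(ch$end, c(399, 199))
  # reference dialect without caller labels defaults every status to "other"
  ts2 <- read_gtf(f, dialect = "reference")
  expect_equal(ts2$transcripts$caller_status, "other")
  expect_equal(ts2$transcripts$gene_status, "other")
})

test_that("GTF writing and re-reading preserves coordinates, strand and labels", {
  ts <- make_ts(list(a = list(start = c(300, 100), end = c(399, 199)),
                     b = list(start = c(500, 700), end = c(520, 780),
                              strand = "+")),
                strand = "-", gene_label = "G9",
                caller_status = c("Known", "Genomic"))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ts, f)
  back <- read_gtf(f, sample_id = "s1")
  expect_equal(dplyr::arrange(back$exons, call_id, exon_rank)[,
                 c("call_id", "exon_rank", "start", "end", "strand")],
               dplyr::arrange(ts$exons, call_id, exon_rank)[,
                 c("call_id", "exon_rank", "start", "end", "strand")])
  expect_equal(sort(back$transcripts$caller_status), c("Genomic", "Known"))
  # second write is byte-identical (round-trip fixed point)
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(back, f2)
  expect_identical(readLines(f), readLines(f2))
  expect_error(write_gtf(make_ts(list())), "empty")
})

test_that("quantification tables are validated and preserved exactly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ttranscript_id\tread_count",
               "s1\tt1\t5", "s1\tt2\t0", "s2\tt1\t12"), f)
  q <- read_quant(f)
  expect_equal(nrow(q), 3)
  expect_identical(q$read_count, c(5, 0, 12))
  writeLines(c("sample_id\ttranscript_id\tread_count",
               "s1\tt1\t5", "s1\tt1\t7"), f)
  expect_error(read_quant(f), "duplicate")
  writeLines(c("sample_id\ttranscript_id\tread_count", "s1\tt1\t-2"), f)
  expect_error(read_quant(f), "non-negative")
})

test_that("BED conversion is an exact bijection on valid records", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr16\t99\t199\tp1\t0\t-", f)
  iv <- read_bed_intervals(f, "tss")
  expect_equal(iv[, c("chrom", "start", "end", "strand")],
               tibble::tibble(chrom = "chr16", start = 100L, end = 199L,
                              strand = "-"))
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed_intervals(iv, f2)
  expect_equal(read_bed_intervals(f2, "tss")[, c("chrom", "start", "end", "strand")],
               iv[, c("chrom", "start", "end", "strand")])
  # empty file and invalid record
  writeLines(character(0), f)
  expect_equal(nrow(read_bed_intervals(f, "pas")), 0)
  writeLines("chr1\t50\t50\tx\t0\t+", f)
  expect_error(read_bed_intervals(f, "tss"), "end <= start")
})

test_that("spliced sequences concatenate and reverse-complement correctly", {
  g <- tiny_genome("AAACGTAACGTTTT")  # positions 4..7 = CGTA
  plus <- tibble::tibble(chrom = "chrT", start = 4, end = 7, strand = "+",
                         exon_rank = 1)
  expect_equal(spliced_sequence(plus, g), "CGTA")
  minus <- plus; minus$strand <- "-"
  expect_equal(spliced_sequence(minus, g), oracle_revcomp("CGTA"))
  # two-exon minus chain equals the reverse complement of the ascending
  # genomic concatenation (independent chartr/rev oracle)
  set.seed(7)
  gseq <- random_dna(300)
  g2 <- tiny_genome(gseq)
  for (i in 1:10) {
    s1 <- sample.int(100, 1); e1 <- s1 + sample.int(40, 1)
    s2 <- e1 + 2 + sample.int(50, 1); e2 <- s2 + sample.int(40, 1)
    ch <- tibble::tibble(chrom = "chrT", start = c(s2, s1), end = c(e2, e1),
                         strand = "-", exon_rank = 1:2)
    expect_equal(spliced_sequence(ch, g2),
                 oracle_revcomp(paste0(substr(gseq, s1, e1),
                                       substr(gseq, s2, e2))))
    expect_equal(nchar(spliced_sequence(ch, g2)),
                 sum(ch$end - ch$start + 1))
  }
  out <- tibble::tibble(chrom = "chrT", start = 290, end = 310,
                        strand = "+", exon_rank = 1)
  expect_error(spliced_sequence(out, g2), "bounds")
})
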