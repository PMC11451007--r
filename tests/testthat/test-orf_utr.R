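test_that("ORF finding applies the longest-per-stop rule", {
  o <- find_orfs("ATGAAATGA")
  expect_equal(nrow(o), 1)
  expect_equal(c(o$tx_start, o$tx_end), c(1L, 9L))
  expect_equal(as.character(Biostrings::translate(
    Biostrings::DNAString("ATGAAA"))), "MK")
  # nested in-frame ATG sharing the stop is absorbed by the longer ORF
  o2 <- find_orfs("ATGATGTAA")
  expect_equal(nrow(o2), 1)
  expect_equal(c(o2$tx_start, o2$tx_end), c(1L, 9L))
  # codons containing N never match start or stop
  orf_n <- find_orfs("ATGAAATNATAA")  # TNA is not a stop; TAA is
  expect_equal(c(orf_n$tx_start, orf_n$tx_end), c(1L, 12L))
  expect_equal(nrow(find_orfs("ANGAAATAA")), 0)
  expect_equal(nrow(find_orfs("")), 0)
})

test_that("ORF finding equals the brute-force oracle", {
  # exhaustive over all sequences of length 3..6
  for (k in 3:6) {
    combos <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), k))
    seqs <- do.call(paste0, combos)
    for (s in seqs) {
      expect_identical(find_orfs(s)[, c("tx_start", "tx_end")],
                       oracle_find_orfs(s), label = s)
    }
  }
  set.seed(13)
  for (i in 1:200) {
    s <- random_dna(120)
    expect_identical(find_orfs(s)[, c("tx_start", "tx_end")],
                     oracle_find_orfs(s), label = s)
  }
})

test_that("ORF selection takes the longest, then the most 5' start", {
  cands <- tibble::tibble(tx_start = c(10, 40), tx_end = c(18, 60),
                          nt_length = c(9, 21))
  expect_equal(select_orf(cands)$tx_start, 40)
  tie <- tibble::tibble(tx_start = c(40, 10), tx_end = c(60, 30),
                        nt_length = c(21, 21))
  expect_equal(select_orf(tie)$tx_start, 10)
  expect_null(select_orf(tie[0, ]))
})

test_that("transcript-to-genome projection matches the per-base oracle", {
  set.seed(23)
  for (strand in c("+", "-")) {
    for (i in 1:10) {
      n_ex <- sample(2:4, 1)
      s <- cumsum(sample(50:120, n_ex)) + (1:n_ex) * 30
      e <- s + sample(20:90, n_ex)
      if (strand == "-") { s <- rev(s); e <- rev(e) }
      ex <- tibble::tibble(chrom = "c", start = s, end = e, strand = strand,
                           exon_rank = 1:n_ex)
      map <- oracle_tx_map(ex)
      a <- sample.int(length(map) - 10, 1); b <- a + sample.int(10, 1)
      blocks <- tx_to_genome(ex, a, b)
      got <- unlist(Map(seq.int, blocks$start, blocks$end))
      expect_equal(sort(got), sort(map[a:b]))
      expect_equal(sum(blocks$end - blocks$start + 1), b - a + 1)
    }
  }
})

test_that("UTR blocks and CDS blocks exactly tile the exon chain", {
  set.seed(31)
  for (i in 1:10) {
    ex <- tibble::tibble(chrom = "c", start = c(500, 300, 100),
                         end = c(560, 390, 180) + sample.int(10, 3),
                         strand = "-", exon_rank = 1:3)
    map <- oracle_tx_map(ex)
    L <- length(map)
    a <- sample(5:30, 1); b <- a + 3 * sample(5:15, 1) - 1
    utrs <- extract_utrs(ex, a, b)
    cds <- tx_to_genome(ex, a, b)
    bases <- function(bl) if (is.null(bl)) integer(0)
             else unlist(Map(seq.int, bl$start, bl$end))
    tiled <- c(bases(utrs$utr5$blocks), bases(cds), bases(utrs$utr3$blocks))
    expect_equal(sort(tiled), sort(map))  # no gaps, no overlaps
    expect_equal(utrs$utr5$distal_end, ex$end[1])
    expect_equal(utrs$utr3$distal_end, ex$start[3])
  }
  # CDS starting at base 1 leaves an empty 5'UTR
  ex1 <- tibble::tibble(chrom = "c", start = 100, end = 199, strand = "+",
                        exon_rank = 1)
  u <- extract_utrs(ex1, 1, 30)
  expect_null(u$utr5$blocks)
  expect_true(is.na(u$utr5$distal_end))
  expect_equal(u$utr3$blocks$start, 130)
})

test_that("the 50-nt NMD rule is strict and junction-based", {
  # two-exon plus-strand chain; last junction at spliced position 200
  chain <- function() tibble::tibble(chrom = "c", start = c(1, 301),
                                     end = c(200, 500), strand = "+",
                                     exon_rank = 1:2)
  for (d in c(49, 50, 51)) {
    expect_equal(predict_nmd(chain(), 200 - d), d > 50)
  }
  single <- tibble::tibble(chrom = "c", start = 1, end = 500, strand = "+",
                           exon_rank = 1)
  expect_false(predict_nmd(single, 100))
  # adding exons upstream of the ORF leaves the call unchanged when the
  # stop-to-last-junction distance is unchanged
  three <- tibble::tibble(chrom = "c", start = c(1, 1001, 2001),
                          end = c(100, 1100, 2200), strand = "+",
                          exon_rank = 1:3)
  # last junction at 200; same distances as the two-exon chain
  for (d in c(49, 51)) expect_equal(predict_nmd(three, 200 - d), d > 50)
})

test_that("ORF identifiers rank by product length with deterministic ties", {
  blocks <- function(s, e) tibble::tibble(chrom = "c", start = s, end = e,
                                          strand = "+")
  anno <- tibble::tibble(
    has_orf = TRUE,
    orf_sig = c("A", "B", "C"),
    protein_length = c(438L, 489L, 181L),
    strand = "+",
    cds_blocks = list(blocks(10, 1326), blocks(5, 1473), blocks(50, 595)))
  ids <- assign_orf_ids(anno, "GENE")
  expect_equal(ids$orf_id[ids$orf_sig == "B"], "GENE_1_489aa")
  expect_equal(ids$orf_id[ids$orf_sig == "A"], "GENE_2_438aa")
  expect_equal(ids$orf_id[ids$orf_sig == "C"], "GENE_3_181aa")
  expect_true(all(grepl("^GENE_\\d+_\\d+aa$", ids$orf_id)))
  # equal-length distinct ORFs get distinct, permutation-stable ranks
  tie <- tibble::tibble(
    has_orf = TRUE, orf_sig = c("X", "Y"), protein_length = c(100L, 100L),
    strand = "+", cds_blocks = list(blocks(200, 502), blocks(100, 402)))
  id1 <- assign_orf_ids(tie, "G")
  id2 <- assign_orf_ids(tie[2:1, ], "G")
  expect_equal(id1, id2[match(id1$orf_sig, id2$orf_sig), ])
  expect_equal(id1$orf_id[id1$orf_sig == "Y"], "G_1_100aa")  # 5'-most start
})

test_that("protein length times three plus three equals CDS length", {
  sim <- small_sim()
  anno <- annotate_transcripts(sim$truth$truth, sim$truth$genome)
  with_orf <- anno[anno$has_orf, ]
  for (i in seq_len(nrow(with_orf))) {
    cds_nt <- with_orf$orf_tx_end[i] - with_orf$orf_tx_start[i] + 1L
    expect_equal(with_orf$protein_length[i] * 3L + 3L, cds_nt)
    expect_equal(sum(with_orf$cds_blocks[[i]]$end -
                       with_orf$cds_blocks[[i]]$start + 1), cds_nt)
  }
})
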