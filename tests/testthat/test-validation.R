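# A merged object whose representatives are the given transcript set.
as_merged <- function(ts) {
  tab <- tibble::tibble(composite_id = ts$transcripts$call_id,
                        rep_sample_id = ts$transcripts$sample_id,
                        rep_call_id = ts$transcripts$call_id,
                        occurrence = 1L)
  structure(list(table = tab,
                 members = tibble::tibble(
                   composite_id = tab$composite_id,
                   sample_id = tab$rep_sample_id,
                   call_id = tab$rep_call_id,
                   read_count = 1),
                 representatives = ts),
            class = "merged_transcripts")
}

test_that("TSS validation measures edge distance with a strict 50-bp bound", {
  # minus-strand transcripts: the 5' terminus is the first exon's genomic end
  ts <- make_ts(list(inside = list(start = c(900, 700), end = c(1000, 750)),
                     at50 = list(start = c(900, 700), end = c(1150, 750)),
                     at51 = list(start = c(900, 700), end = c(1151, 750))),
                strand = "-")
  peaks <- tibble::tibble(chrom = "chrT", start = 990, end = 1100,
                          strand = "-", kind = "tss")
  v <- validate_tss(as_merged(ts), peaks)
  expect_equal(v$validated, c(TRUE, TRUE, FALSE))
  expect_equal(v$distance, c(0, 50, 51))
  expect_equal(attr(v, "fraction"), 2 / 3)
  expect_warning(v0 <- validate_tss(as_merged(ts), peaks[0, ]), "empty")
  expect_true(all(!v0$validated))
  # monotone in tolerance: a larger window never unflags
  v2 <- validate_tss(as_merged(ts), peaks, validation_params(tss_tolerance = 80))
  expect_true(all(v2$validated >= v$validated))
})

test_that("PAS validation mirrors TSS validation on the 3' terminus", {
  ts <- make_ts(list(hit = list(start = c(900, 700), end = c(1000, 750)),
                     miss = list(start = c(900, 500), end = c(1000, 550))),
                strand = "-")
  cl <- tibble::tibble(chrom = "chrT", start = 690, end = 710, strand = "*",
                       kind = "pas")
  v <- validate_pas(as_merged(ts), cl)
  expect_equal(v$validated, c(TRUE, FALSE))
})

test_that("junction matching is exact and self-matching is complete", {
  ts <- make_ts(list(a = list(start = c(900, 700), end = c(1000, 750))),
                strand = "-")
  introns <- tx_introns(exon_chain(ts, "s1", "a"))
  expect_equal(introns$start, 751)
  expect_equal(introns$end, 899)
  ref <- tibble::tibble(chrom = "chrT", intron_start = 751, intron_end = 899,
                        strand = "-")
  expect_true(validate_junctions(as_merged(ts), ref)$matched)
  shifted <- dplyr::mutate(ref, intron_start = 752)
  expect_false(validate_junctions(as_merged(ts), shifted)$matched)
  # reference built from the merged set itself matches 100%
  sim <- small_sim()
  merged_ref <- tibble::tibble(chrom = sim$truth$all_introns$chrom,
                               intron_start = sim$truth$all_introns$start,
                               intron_end = sim$truth$all_introns$end,
                               strand = sim$truth$all_introns$strand)
  truth_merged <- as_merged(sim$truth$truth)
  jv <- validate_junctions(truth_merged, merged_ref)
  expect_equal(attr(jv, "fraction"), 1)
})

test_that("junction detection rates match an independent tabulation", {
  jx <- tibble::tibble(chrom = "c", intron_start = 10, intron_end = 20,
                       strand = "+", s1 = 0, s2 = 0, s3 = 2)
  st <- tibble::tibble(sample_id = c("s1", "s2", "s3"), tissue = "liver")
  r <- junction_detection_rates(jx, st)
  expect_equal(r$per_tissue$detection_rate, 1 / 3)
  expect_equal(r$per_tissue$mean_count, 2 / 3)
  jx0 <- dplyr::mutate(jx, s3 = 0)
  r0 <- junction_detection_rates(jx0, st)
  expect_equal(r0$per_tissue$detection_rate, 0)
  expect_equal(r0$per_tissue$mean_count, 0)
  # random Poisson counts, two tissues, versus direct tabulation
  set.seed(29)
  wide <- tibble::tibble(chrom = "c", intron_start = c(1, 100),
                         intron_end = c(50, 150), strand = "+")
  samples <- paste0("s", 1:8)
  for (s in samples) wide[[s]] <- rpois(2, 1.2)
  st2 <- tibble::tibble(sample_id = samples,
                        tissue = rep(c("A", "B"), each = 4))
  r2 <- junction_detection_rates(wide, st2)
  for (i in 1:2) {
    for (tt in c("A", "B")) {
      cols <- st2$sample_id[st2$tissue == tt]
      counts <- as.numeric(wide[i, cols])
      row <- r2$per_tissue[r2$per_tissue$intron_start == wide$intron_start[i] &
                             r2$per_tissue$tissue == tt, ]
      expect_equal(row$detection_rate, mean(counts > 0))
      expect_equal(row$mean_count, mean(counts))
    }
    srow <- r2$summary[r2$summary$intron_start == wide$intron_start[i], ]
    tm <- r2$per_tissue$mean_count[r2$per_tissue$intron_start ==
                                     wide$intron_start[i]]
    expect_equal(c(srow$min_mean, srow$mean_mean, srow$max_mean),
                 c(min(tm), mean(tm), max(tm)))
  }
})

test_that("exon identity screening reports exact sequence matches only", {
  set.seed(37)
  seq <- random_dna(400)
  # plant a duplicated exon: positions 51..100 == 201..250
  seq <- paste0(substr(seq, 1, 200), substr(seq, 51, 100),
                substr(seq, 251, 400))
  g <- tiny_genome(seq)
  a <- tibble::tibble(chrom = "chrT", start = 51, end = 100, strand = "+")
  b <- tibble::tibble(chrom = "chrT", start = c(201, 301),
                      end = c(250, 350), strand = "+")
  hits <- exon_identity_screen(a, b, g)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$b_start, 201)
  expect_equal(hits$seq_length, 50)
  # 1-bp off is no longer identical
  b2 <- dplyr::mutate(b[1, ], start = start + 1, end = end + 1)
  expect_equal(nrow(exon_identity_screen(a, b2, g)), 0)
  # self-screen: every exon matches itself
  self <- exon_identity_screen(b, b, g)
  expect_true(all(paste(b$start, b$end) %in% paste(self$a_start, self$a_end)))
})

test_that("tryptic digestion cleaves after K/R except before P", {
  expect_equal(tryptic_peptides("MKRPAAAKLLLRTTTK"),
               c("MK", "RPAAAK", "LLLR", "TTTK"))
  expect_equal(tryptic_peptides(""), character(0))
})

test_that("unique peptides are absent from the background by substring scan", {
  prot <- "MKAAAAAAKWWWWWWRCCCCCCK"
  expect_equal(unique_peptides(prot, prot), character(0))
  bg <- "MKAAAAAAKCCCCCCK"  # lacks the W stretch
  up <- unique_peptides(prot, bg)
  expect_equal(up, "WWWWWWR")
  expect_true(all(!vapply(up, grepl, logical(1), x = bg, fixed = TRUE)))
  # peptides below the length floor are never reported
  expect_false("MK" %in% unique_peptides(prot, "ZZZ"))
})
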