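mini_merged <- function(counts) {
  # counts: named list tx -> named vector sample -> reads
  members <- dplyr::bind_rows(lapply(names(counts), function(tx) {
    tibble::tibble(composite_id = tx, sample_id = names(counts[[tx]]),
                   call_id = paste0(tx, ".", names(counts[[tx]])),
                   read_count = unname(counts[[tx]]))
  }))
  structure(list(table = tibble::tibble(composite_id = names(counts)),
                 members = members),
            class = "merged_transcripts")
}

test_that("usage is the per-sample fraction of locus reads", {
  um <- usage_matrix(mini_merged(list(a = c(s1 = 30), b = c(s1 = 70))))
  expect_equal(sort(um$usage), c(0.3, 0.7))
  one <- usage_matrix(mini_merged(list(a = c(s1 = 12))))
  expect_equal(one$usage, 1)
  # conservation for arbitrary count configurations
  set.seed(9)
  counts <- lapply(setNames(nm = paste0("t", 1:6)), function(i)
    setNames(sample.int(500, 8), paste0("s", 1:8)))
  um2 <- usage_matrix(mini_merged(counts))
  sums <- um2 |> dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(usage))
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("median usage is computed over detection-positive samples only", {
  um <- tibble::tibble(composite_id = "t",
                       sample_id = paste0("s", 1:3),
                       usage = c(0.1, 0.3, 0.5), detected = TRUE)
  expect_equal(median_usage(um)$median_usage, 0.3)
  sparse <- tibble::tibble(composite_id = "t",
                           sample_id = paste0("s", 1:5),
                           usage = c(0.4, 0, 0, 0, 0),
                           detected = c(TRUE, rep(FALSE, 4)))
  m <- median_usage(sparse)
  expect_equal(m$median_usage, 0.4)  # zeros outside detection ignored
  expect_equal(m$n_detected, 1)
  never <- tibble::tibble(composite_id = "t", sample_id = "s1", usage = 0,
                          detected = FALSE)
  expect_error(median_usage(never), "never detected")
})

test_that("ORF usage sums transcripts sharing an ORF and stays normalized", {
  um <- usage_matrix(mini_merged(list(a = c(s1 = 20), b = c(s1 = 30),
                                      c = c(s1 = 50))))
  map <- tibble::tibble(composite_id = c("a", "b", "c"),
                        orf_id = c("O1", "O1", "O2"))
  ou <- orf_usage(um, map)
  expect_equal(ou$usage[ou$orf_id == "O1"], 0.5)
  expect_equal(sum(ou$usage), 1)
  # distinct ORFs reduce to transcript usage
  map2 <- tibble::tibble(composite_id = c("a", "b", "c"),
                         orf_id = c("O1", "O2", "O3"))
  ou2 <- orf_usage(um, map2)
  expect_equal(sort(ou2$usage), c(0.2, 0.3, 0.5))
})

test_that("tissue specificity uses the inclusive two-fold rule on tissue means", {
  um <- tibble::tibble(
    composite_id = "t",
    sample_id = paste0("s", 1:6),
    usage = c(0.4, 0.4, 0.2, 0.2, 0.1, 0.1), detected = TRUE)
  tiss <- tibble::tibble(sample_id = paste0("s", 1:6),
                         tissue = rep(c("A", "B", "C"), each = 2))
  expect_equal(tissue_specific(um, tiss)$specific_tissue, "A")  # 0.4 >= 2*0.2
  um$usage <- c(0.4, 0.4, 0.25, 0.25, 0.1, 0.1)
  expect_true(is.na(tissue_specific(um, tiss)$specific_tissue))
  # present in a single tissue only -> specific to it
  um$usage <- c(0, 0, 0.3, 0.3, 0, 0)
  expect_equal(tissue_specific(um, tiss)$specific_tissue, "B")
  one_tissue <- tibble::tibble(sample_id = paste0("s", 1:2), tissue = "A")
  expect_warning(out <- tissue_specific(um[1:2, ], one_tissue),
                 "fewer than two")
  expect_true(all(is.na(out$specific_tissue)))
})

test_that("the reference processed against itself yields zero novel items", {
  sim <- small_sim()
  tr <- sim$truth
  ref_target <- assign_to_locus(tr$reference, tr$locus)
  keys <- ref_target$transcripts[ref_target$transcripts$locus_label == "target",
                                 c("sample_id", "call_id")]
  ref_ts <- subset_calls(tr$reference, keys)
  ref_anno <- annotate_transcripts(ref_ts, tr$genome)
  ids <- assign_orf_ids(ref_anno, "R")
  ref_anno$orf_id <- ids$orf_id[match(ref_anno$orf_sig, ids$orf_sig)]
  ref_anno$orf_id[!ref_anno$has_orf] <- "noORF"
  a5 <- cluster_utrs(tibble::tibble(internal_sig = ref_anno$utr5_sig,
                                    distal_end = ref_anno$utr5_distal,
                                    support = 1), "5")
  a3 <- cluster_utrs(tibble::tibble(internal_sig = ref_anno$utr3_sig,
                                    distal_end = ref_anno$utr3_distal,
                                    support = 1), "3")
  ref_anno$utr5_id <- a5$utr_id
  ref_anno$utr3_id <- a3$utr_id
  merged <- merge_calls(ref_anno, ref_ts)
  flags <- novelty_flags(merged, ref_anno, ref_anno)
  expect_true(all(flags$orf_known | merged$table$orf_id == "noORF"))
  expect_true(all(flags$utr5_known))
  expect_true(all(flags$utr3_known))
  expect_true(all(flags$tx_known))
  expect_warning(novelty_flags(merged, ref_anno, ref_anno[0, ]),
                 "empty reference")
})

test_that("the category cascade is total, exclusive and NMD-first", {
  p <- classify_params()
  grid <- expand.grid(nmd = c(TRUE, FALSE), tx_known = c(TRUE, FALSE),
                      orf_known = c(TRUE, FALSE),
                      utr5_known = c(TRUE, FALSE),
                      utr3_known = c(TRUE, FALSE),
                      protein_length = c(149L, 150L, NA))
  grid$has_orf <- !is.na(grid$protein_length)
  cat <- classify_category(grid$nmd, grid$has_orf, grid$protein_length,
                           grid$tx_known, grid$orf_known, grid$utr5_known,
                           grid$utr3_known, p)
  expect_false(anyNA(cat))  # cascade is total
  expect_true(all(cat[grid$nmd] %in% c("NMD_Known", "NMD_Novel")))
  # strict < 150 aa bound
  expect_equal(unique(cat[!grid$nmd & grid$tx_known &
                            !is.na(grid$protein_length) &
                            grid$protein_length == 149]), "Non_coding_Known")
  expect_equal(unique(cat[!grid$nmd & grid$tx_known &
                            !is.na(grid$protein_length) &
                            grid$protein_length == 150]), "Coding_Known")
  # known ORF and UTRs but unseen pairing
  expect_equal(classify_category(FALSE, TRUE, 300L, FALSE, TRUE, TRUE, TRUE, p),
               "Novel_combination")
  expect_equal(classify_category(FALSE, TRUE, 300L, FALSE, TRUE, FALSE, TRUE, p),
               "Novel_3/5UTR_only")
  expect_equal(classify_category(FALSE, TRUE, 300L, FALSE, FALSE, TRUE, FALSE, p),
               "Novel_ORF_and_UTR")
  expect_equal(classify_category(FALSE, TRUE, 300L, FALSE, FALSE, TRUE, TRUE, p),
               "Novel_ORF_only")
  expect_equal(classify_category(TRUE, TRUE, 300L, FALSE, FALSE, TRUE, TRUE, p),
               "NMD_Novel")
})
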