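# Independent oracles and small fixture builders used across the suite.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force ORF oracle: enumerate every in-frame ATG..stop pair with no
# intervening in-frame stop, then keep the longest ORF per stop. Independent
# of the scanning implementation in the package.
oracle_find_orfs <- function(seq) {
  n <- nchar(seq)
  starts <- integer(0); ends <- integer(0)
  stops <- c("TAA", "TAG", "TGA")
  for (s in seq_len(max(n - 5, 0))) {
    if (substr(seq, s, s + 2) != "ATG") next
    e <- s + 3
    while (e + 2 <= n) {
      codon <- substr(seq, e, e + 2)
      if (codon %in% stops) {
        starts <- c(starts, s); ends <- c(ends, e + 2)
        break
      }
      e <- e + 3
    }
  }
  if (!length(starts)) {
    return(tibble::tibble(tx_start = integer(0), tx_end = integer(0)))
  }
  d <- tibble::tibble(tx_start = starts, tx_end = ends)
  d <- do.call(rbind, lapply(split(d, d$tx_end), function(g) {
    g[which.min(g$tx_start), ]
  }))
  d <- d[order(d$tx_start, d$tx_end), ]
  tibble::tibble(tx_start = as.integer(d$tx_start),
                 tx_end = as.integer(d$tx_end))
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Per-base transcript-to-genome projection oracle.
oracle_tx_map <- function(exons) {
  exons <- exons[order(exons$exon_rank), ]
  unlist(lapply(seq_len(nrow(exons)), function(i) {
    if (exons$strand[i] == "+") exons$start[i]:exons$end[i]
    else exons$end[i]:exons$start[i]
  }))
}

tiny_genome <- function(seq, chrom = "chrT") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- chrom
  g
}

# transcript_set with one call per element of `chains`; each chain is a
# list(start=, end=) in transcript order (plus optional strand/chrom).
make_ts <- function(chains, strand = "+", chrom = "chrT", sample_id = "s1",
                    read_count = 10, caller_status = "other",
                    gene_status = "other", gene_label = "G") {
  ids <- names(chains)
  if (is.null(ids)) ids <- paste0("tx", seq_along(chains))
  if (!length(chains)) {
    empty_ex <- tibble::tibble(sample_id = character(), call_id = character(),
                               exon_rank = integer(), chrom = character(),
                               start = numeric(), end = numeric(),
                               strand = character())
    empty_tx <- tibble::tibble(sample_id = character(), call_id = character(),
                               gene_label = character(),
                               caller_status = character(),
                               gene_status = character(),
                               read_count = numeric())
    return(transcript_set(empty_tx, empty_ex))
  }
  ex <- dplyr::bind_rows(lapply(seq_along(chains), function(i) {
    ch <- chains[[i]]
    tibble::tibble(sample_id = sample_id, call_id = ids[i],
                   exon_rank = seq_along(ch$start), chrom = chrom,
                   start = ch$start, end = ch$end,
                   strand = if (!is.null(ch$strand)) ch$strand else strand)
  }))
  tx <- tibble::tibble(sample_id = sample_id, call_id = ids,
                       gene_label = gene_label,
                       caller_status = rep_len(caller_status, length(ids)),
                       gene_status = rep_len(gene_status, length(ids)),
                       read_count = rep_len(read_count, length(ids)))
  transcript_set(tx, ex)
}

# A small cached simulation used by several test files (built once per run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_samples = 9,
                        tissues = c(brain = 3, heart = 3, blood = 3),
                        dropout = 0, utr_jitter_bp = 0)
      tr <- build_truth(cfg)
      sim <- simulate_samples(tr, cfg)
      cache <<- list(cfg = cfg, truth = tr, sim = sim)
    }
    cache
  }
})

# Map composite_id back to the truth transcript names via member call ids.
truth_of_merged <- function(merged) {
  m <- merged$members
  m$truth <- sub("\\..*$", "", m$call_id)
  unique(m[, c("composite_id", "truth")])
}
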