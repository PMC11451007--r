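#' Parameters for ORF prediction and NMD calling
#'
#' @param start_codon Start codon (default `"ATG"`).
#' @param stop_codons Stop codons (default `TAA`, `TAG`, `TGA`).
#' @param nmd_distance The 50-nt rule distance: a transcript is called
#'   NMD-sensitive when its stop codon ends more than this many nucleotides
#'   upstream of the most downstream exon-exon junction.
#' @return An `orf_params` list.
#' @export
orf_params <- function(start_codon = "ATG",
                       stop_codons = c("TAA", "TAG", "TGA"),
                       nmd_distance = 50L) {
  stopifnot(nmd_distance > 0)
  structure(list(start_codon = start_codon, stop_codons = stop_codons,
                 nmd_distance = as.integer(nmd_distance)),
            class = "orf_params")
}

#' Find candidate ORFs on a spliced sequence
#'
#' Scans all three frames for in-frame start..stop segments. For each
#' distinct stop codon only the longest ORF (most upstream start) is kept.
#' ORFs lacking an in-frame stop before the end of the sequence are
#' discarded. Codons containing `N` never match the start or stop codons.
#'
#' @param seq Nucleotide string over `A`,`C`,`G`,`T`,`N`.
#' @param params An [orf_params()].
#' @return Tibble with `tx_start`, `tx_end` (1-based, stop codon included)
#'   and `nt_length`, ordered by position.
#' @export
find_orfs <- function(seq, params = orf_params()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out_start <- integer(0); out_end <- integer(0)
  if (n >= 6) {
    for (f in 0:2) {
      starts <- seq.int(f + 1L, n, by = 3L)
      starts <- starts[starts + 2L <= n]
      if (!length(starts)) next
      codons <- substring(seq, starts, starts + 2L)
      is_start <- codons == params$start_codon
      is_stop <- codons %in% params$stop_codons
      open <- NA_integer_
      for (i in seq_along(codons)) {
        if (is_stop[i]) {
          if (!is.na(open)) {
            out_start <- c(out_start, open)
            out_end <- c(out_end, starts[i] + 2L)
          }
          open <- NA_integer_
        } else if (is_start[i] && is.na(open)) {
          open <- starts[i]
        }
      }
    }
  }
  o <- order(out_start, out_end)
  tibble::tibble(tx_start = out_start[o], tx_end = out_end[o],
                 nt_length = out_end[o] - out_start[o] + 1L)
}

#' Select the single ORF of a transcript
#'
#' The longest candidate wins; on a length tie the most 5' start wins
#' (deterministic, permutation-stable).
#'
#' @param candidates Tibble from [find_orfs()].
#' @return One-row tibble, or `NULL` when there is no candidate.
#' @export
select_orf <- function(candidates) {
  if (is.null(candidates) || !nrow(candidates)) return(NULL)
  o <- order(-candidates$nt_length, candidates$tx_start)
  candidates[o[1], , drop = FALSE]
}

#' Project a transcript-coordinate interval onto the genome
#'
#' Maps a spliced-transcript interval through an exon chain, splitting it at
#' exon junctions; strand-aware (minus-strand chains run genomically
#' downwards).
#'
#' @param exons One exon chain tibble ordered by `exon_rank`.
#' @param tx_from,tx_to Transcript-relative 1-based positions,
#'   `tx_from <= tx_to`.
#' @return Tibble of genomic blocks (`chrom`, `start`, `end`, `strand`) in
#'   transcript order; total width equals `tx_to - tx_from + 1`.
#' @export
tx_to_genome <- function(exons, tx_from, tx_to) {
  exons <- exons[order(exons$exon_rank), ]
  w <- exons$end - exons$start + 1L
  cum_end <- cumsum(w)
  cum_start <- cum_end - w + 1L
  stopifnot(tx_from >= 1, tx_to <= cum_end[length(w)], tx_from <= tx_to)
  rows <- which(cum_end >= tx_from & cum_start <= tx_to)
  blocks <- lapply(rows, function(i) {
    a <- max(tx_from, cum_start[i]) - cum_start[i]  # offset within exon
    b <- min(tx_to, cum_end[i]) - cum_start[i]
    if (exons$strand[i] == "+") {
      c(exons$start[i] + a, exons$start[i] + b)
    } else {
      c(exons$end[i] - b, exons$end[i] - a)
    }
  })
  tibble::tibble(chrom = exons$chrom[rows],
                 start = vapply(blocks, `[`, numeric(1), 1),
                 end = vapply(blocks, `[`, numeric(1), 2),
                 strand = exons$strand[rows])
}

block_sig <- function(blocks) {
  if (is.null(blocks) || !nrow(blocks)) return("")
  b <- blocks[order(blocks$start), ]
  paste0(b$chrom[1], b$strand[1], ":",
         paste(b$start, b$end, sep = "-", collapse = ","))
}

tx_terminus <- function(exons, side) {
  exons <- exons[order(exons$exon_rank), ]
  minus <- exons$strand[1] == "-"
  if (side == "5") {
    if (minus) exons$end[1] else exons$start[1]
  } else {
    n <- nrow(exons)
    if (minus) exons$start[n] else exons$end[n]
  }
}

# All block edges except the distal transcript terminus, as a signature.
utr_internal_sig <- function(blocks, exclude) {
  if (is.null(blocks) || !nrow(blocks)) return("")
  edges <- sort(c(blocks$start, blocks$end))
  drop <- match(exclude, edges)
  drop <- drop[!is.na(drop)]
  if (length(drop)) edges <- edges[-drop]
  paste0(blocks$chrom[1], blocks$strand[1], ":",
         paste(edges, collapse = ","))
}

#' Decompose a transcript into 5'UTR and 3'UTR blocks around its ORF
#'
#' The 5'UTR is the spliced region upstream of the start codon; the 3'UTR is
#' the region downstream of the stop codon. Either may be empty. Each record
#' carries the genomic blocks, the set of internal boundaries (all block
#' edges except the distal transcript terminus) and the distal terminus
#' itself -- the quantities the cross-sample merge criteria are defined on.
#'
#' @param exons One exon chain tibble ordered by `exon_rank`.
#' @param orf_tx_start,orf_tx_end Transcript coordinates of the CDS
#'   (stop codon included).
#' @return List with elements `utr5` and `utr3`, each a list
#'   `(side, blocks, internal_sig, distal_end)`.
#' @export
extract_utrs <- function(exons, orf_tx_start, orf_tx_end) {
  exons <- exons[order(exons$exon_rank), ]
  tx_len <- sum(exons$end - exons$start + 1L)
  mk <- function(side, from, to) {
    if (from > to) {
      return(list(side = side, blocks = NULL, internal_sig = "",
                  distal_end = NA_real_))
    }
    blocks <- tx_to_genome(exons, from, to)
    distal <- tx_terminus(exons, side)
    list(side = side, blocks = blocks,
         internal_sig = utr_internal_sig(blocks, distal),
         distal_end = distal)
  }
  list(utr5 = mk("5", 1L, orf_tx_start - 1L),
       utr3 = mk("3", orf_tx_end + 1L, tx_len))
}

#' Predict nonsense-mediated decay by the 50-nt rule
#'
#' `TRUE` when the 3' end of the stop codon lies more than
#' `params$nmd_distance` nucleotides (spliced coordinates) upstream of the
#' most downstream exon-exon junction; single-exon transcripts are never
#' NMD-sensitive.
#'
#' @param exons One exon chain tibble ordered by `exon_rank`.
#' @param orf_tx_end Transcript coordinate of the last base of the stop
#'   codon.
#' @param params An [orf_params()].
#' @return Logical scalar.
#' @export
predict_nmd <- function(exons, orf_tx_end, params = orf_params()) {
  n <- nrow(exons)
  if (n < 2L) return(FALSE)
  exons <- exons[order(exons$exon_rank), ]
  w <- exons$end - exons$start + 1L
  last_junction <- sum(w[-n])
  (last_junction - orf_tx_end) > params$nmd_distance
}

translate_cds <- function(cds_seq) {
  aa <- Biostrings::translate(Biostrings::DNAString(cds_seq),
                              if.fuzzy.codon = "X")
  as.character(aa)
}

#' Annotate every call with its ORF, UTRs and NMD status
#'
#' Runs ORF prediction (longest per stop codon, then longest per transcript)
#' on each call's spliced sequence, projects the CDS to genomic blocks,
#' decomposes the UTRs, and applies the 50-nt NMD rule. Transcripts with no
#' ORF get pseudo-UTR records spanning the whole exon structure (internal
#' boundaries = all edges except both termini) so they can still be merged
#' on structural identity with end tolerance.
#'
#' @param ts A [transcript_set()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @param params An [orf_params()].
#' @return Tibble with one row per call: ORF transcript coordinates, protein
#'   length and sequence, genomic CDS-block signature (`orf_sig`), UTR
#'   internal-boundary signatures and distal ends, and the `nmd` flag.
#'   CDS and UTR blocks are kept as list columns.
#' @export
annotate_transcripts <- function(ts, genome, params = orf_params()) {
  tx <- ts$transcripts
  rows <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    ex <- exon_chain(ts, tx$sample_id[i], tx$call_id[i])
    seq <- spliced_sequence(ex, genome)
    orf <- select_orf(find_orfs(seq, params))
    tx_len <- nchar(seq)
    if (is.null(orf)) {
      edges <- sort(c(ex$start, ex$end))
      t5 <- tx_terminus(ex, "5"); t3 <- tx_terminus(ex, "3")
      internal <- edges[!edges %in% c(t5, t3)]
      sig <- paste0(ex$chrom[1], ex$strand[1], ":",
                    paste(internal, collapse = ","))
      rows[[i]] <- tibble::tibble(
        sample_id = tx$sample_id[i], call_id = tx$call_id[i],
        chrom = ex$chrom[1], strand = ex$strand[1],
        tx_len = tx_len, n_exons = nrow(ex), has_orf = FALSE,
        orf_tx_start = NA_integer_, orf_tx_end = NA_integer_,
        protein_length = NA_integer_, protein_seq = NA_character_,
        orf_sig = "noORF", cds_blocks = list(NULL),
        utr5_sig = sig, utr5_distal = t5, utr5_blocks = list(NULL),
        utr3_sig = sig, utr3_distal = t3, utr3_blocks = list(NULL),
        nmd = FALSE)
      next
    }
    cds_blocks <- tx_to_genome(ex, orf$tx_start, orf$tx_end)
    utrs <- extract_utrs(ex, orf$tx_start, orf$tx_end)
    prot <- translate_cds(substr(seq, orf$tx_start, orf$tx_end - 3L))
    rows[[i]] <- tibble::tibble(
      sample_id = tx$sample_id[i], call_id = tx$call_id[i],
      chrom = ex$chrom[1], strand = ex$strand[1],
      tx_len = tx_len, n_exons = nrow(ex), has_orf = TRUE,
      orf_tx_start = orf$tx_start, orf_tx_end = orf$tx_end,
      protein_length = nchar(prot), protein_seq = prot,
      orf_sig = block_sig(cds_blocks), cds_blocks = list(cds_blocks),
      utr5_sig = utrs$utr5$internal_sig, utr5_distal = utrs$utr5$distal_end,
      utr5_blocks = list(utrs$utr5$blocks),
      utr3_sig = utrs$utr3$internal_sig, utr3_distal = utrs$utr3$distal_end,
      utr3_blocks = list(utrs$utr3$blocks),
      nmd = predict_nmd(ex, orf$tx_end, params))
  }
  anno <- dplyr::bind_rows(rows)
  anno$read_count <- tx$read_count[match(paste(anno$sample_id, anno$call_id),
                                         paste(tx$sample_id, tx$call_id))]
  anno
}

#' Assign length-rank ORF identifiers
#'
#' Distinct ORFs (keyed by genomic CDS block structure) are ranked by
#' descending protein length; ties break by 5'-most genomic CDS start, then
#' by block signature, so the assignment is deterministic under input
#' permutation. IDs have the form `"{gene}_{rank}_{length}aa"`. The rank
#' catalog may include reference ORFs supplied via `extra`.
#'
#' @param anno Annotation tibble from [annotate_transcripts()].
#' @param gene Gene name used as the ID prefix.
#' @param extra Optional second annotation tibble whose ORFs enter the rank
#'   catalog (e.g. the reference annotation's).
#' @return Tibble `orf_catalog` (`orf_sig`, `orf_id`, `orf_rank`,
#'   `protein_length`); join it to annotations by `orf_sig`.
#' @export
assign_orf_ids <- function(anno, gene, extra = NULL) {
  cat_in <- dplyr::bind_rows(anno, extra)
  cat_in <- cat_in[cat_in$has_orf, ]
  if (!nrow(cat_in)) {
    return(tibble::tibble(orf_sig = character(), orf_id = character(),
                          orf_rank = integer(), protein_length = integer()))
  }
  five_start <- function(blocks, strand) {
    if (strand == "+") min(blocks$start) else -max(blocks$end)
  }
  catalog <- cat_in |>
    dplyr::group_by(.data$orf_sig) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  fp <- mapply(five_start, catalog$cds_blocks, catalog$strand)
  o <- order(-catalog$protein_length, fp, catalog$orf_sig)
  catalog <- catalog[o, ]
  tibble::tibble(orf_sig = catalog$orf_sig,
                 orf_id = sprintf("%s_%d_%daa", gene,
                                  seq_len(nrow(catalog)),
                                  catalog$protein_length),
                 orf_rank = seq_len(nrow(catalog)),
                 protein_length = catalog$protein_length)
}
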