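#' Parameters for external-evidence validation
#' @param tss_tolerance Max distance (bp) from a transcript 5' terminus to
#'   the nearest TSS peak (default 50).
#' @param pas_tolerance Max distance (bp) from a transcript 3' terminus to
#'   the nearest polyA-site cluster (default 50).
#' @return A `validation_params` list.
#' @export
validation_params <- function(tss_tolerance = 50L, pas_tolerance = 50L) {
  stopifnot(tss_tolerance >= 0, pas_tolerance >= 0)
  structure(list(tss_tolerance = as.integer(tss_tolerance),
                 pas_tolerance = as.integer(pas_tolerance)),
            class = "validation_params")
}

# Distance from a genomic point to the nearest compatible interval edge
# (0 inside). Strand "*" on either side is strand-agnostic.
point_to_intervals <- function(chrom, pos, strand, intervals) {
  ok <- intervals$chrom == chrom &
    (intervals$strand == "*" | strand == "*" | intervals$strand == strand)
  if (!any(ok)) return(Inf)
  iv <- intervals[ok, ]
  min(pmax(0, iv$start - pos, pos - iv$end))
}

merged_termini <- function(merged, side) {
  tab <- merged$table
  reps <- merged$representatives
  pos <- numeric(nrow(tab)); chrom <- character(nrow(tab))
  strand <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    ex <- exon_chain(reps, tab$rep_sample_id[i], tab$rep_call_id[i])
    pos[i] <- tx_terminus(ex, side)
    chrom[i] <- ex$chrom[1]
    strand[i] <- ex$strand[1]
  }
  tibble::tibble(composite_id = tab$composite_id, chrom = chrom,
                 pos = pos, strand = strand)
}

validate_end <- function(merged, intervals, tol, side, label) {
  ends <- merged_termini(merged, side)
  if (is.null(intervals) || !nrow(intervals)) {
    warning("empty ", label, " reference set: nothing validated")
    d <- rep(Inf, nrow(ends))
  } else {
    d <- mapply(point_to_intervals, ends$chrom, ends$pos, ends$strand,
                MoreArgs = list(intervals = intervals), USE.NAMES = FALSE)
  }
  out <- tibble::tibble(composite_id = ends$composite_id,
                        distance = d, validated = d <= tol)
  attr(out, "fraction") <- mean(out$validated)
  out
}

#' Validate transcription start sites against a TSS peak atlas
#'
#' A transcript's TSS is validated when its 5' genomic terminus lies within
#' `tss_tolerance` of the nearest same-strand peak interval (distance 0
#' inside a peak).
#'
#' @param merged A `merged_transcripts` object.
#' @param tss_peaks Interval tibble from [read_bed_intervals()].
#' @param params A [validation_params()].
#' @return Tibble with `composite_id`, `distance`, `validated`; the summary
#'   fraction is in `attr(, "fraction")`.
#' @export
validate_tss <- function(merged, tss_peaks, params = validation_params()) {
  validate_end(merged, tss_peaks, params$tss_tolerance, "5", "TSS")
}

#' Validate polyadenylation sites against a polyA-site atlas
#'
#' As [validate_tss()], for the 3' terminus against polyA-site clusters
#' within `pas_tolerance`.
#'
#' @inheritParams validate_tss
#' @param pas_clusters Interval tibble from [read_bed_intervals()].
#' @return Tibble with `composite_id`, `distance`, `validated`; summary
#'   fraction in `attr(, "fraction")`.
#' @export
validate_pas <- function(merged, pas_clusters, params = validation_params()) {
  validate_end(merged, pas_clusters, params$pas_tolerance, "3", "PAS")
}

#' Introns of an exon chain
#' @param exons One exon chain tibble ordered by `exon_rank`.
#' @return Tibble of intron intervals (`chrom`, `start`, `end`, `strand`),
#'   1-based inclusive first-to-last intronic base; empty for single-exon
#'   chains.
#' @export
tx_introns <- function(exons) {
  exons <- exons[order(exons$exon_rank), ]
  n <- nrow(exons)
  if (n < 2L) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), strand = character()))
  }
  minus <- exons$strand[1] == "-"
  if (minus) {
    start <- exons$end[-1] + 1
    end <- exons$start[-n] - 1
  } else {
    start <- exons$end[-n] + 1
    end <- exons$start[-1] - 1
  }
  tibble::tibble(chrom = exons$chrom[1], start = start, end = end,
                 strand = exons$strand[1])
}

distinct_introns <- function(merged) {
  tab <- merged$table
  reps <- merged$representatives
  all_introns <- lapply(seq_len(nrow(tab)), function(i) {
    tx_introns(exon_chain(reps, tab$rep_sample_id[i], tab$rep_call_id[i]))
  })
  dplyr::distinct(dplyr::bind_rows(all_introns))
}

#' Match the merged set's splice junctions against a reference junction set
#'
#' Junctions are intron intervals; a junction is matched only on exact
#' coordinate and strand equality (a reference strand of `"*"` matches
#' either strand).
#'
#' @param merged A `merged_transcripts` object.
#' @param junctions Reference junction tibble with `chrom`, `intron_start`,
#'   `intron_end`, `strand` (e.g. from [read_junctions()]).
#' @return Tibble of the merged set's distinct introns with a `matched`
#'   flag; matched fraction in `attr(, "fraction")`.
#' @export
validate_junctions <- function(merged, junctions) {
  introns <- distinct_introns(merged)
  if (!nrow(introns)) {
    attr(introns, "fraction") <- NaN
    introns$matched <- logical(0)
    return(introns)
  }
  matched <- vapply(seq_len(nrow(introns)), function(i) {
    any(junctions$chrom == introns$chrom[i] &
          junctions$intron_start == introns$start[i] &
          junctions$intron_end == introns$end[i] &
          (junctions$strand == "*" | junctions$strand == introns$strand[i]))
  }, logical(1))
  introns$matched <- matched
  attr(introns, "fraction") <- mean(matched)
  introns
}

#' Per-tissue junction detection rates and mean counts
#'
#' For each junction and tissue: detection rate = fraction of the tissue's
#' samples with count > 0; mean count = average over all the tissue's
#' samples (zeros included). The per-junction summary reports the minimum,
#' mean and maximum of the per-tissue mean counts.
#'
#' @param junction_counts Wide tibble from [read_junctions()]: `chrom`,
#'   `intron_start`, `intron_end`, `strand`, then one count column per
#'   sample.
#' @param sample_tissues Tibble with `sample_id`, `tissue`.
#' @return List with `per_tissue` (junction x tissue rates and means) and
#'   `summary` (per-junction min/mean/max of tissue means).
#' @export
junction_detection_rates <- function(junction_counts, sample_tissues) {
  key_cols <- c("chrom", "intron_start", "intron_end", "strand")
  long <- junction_counts |>
    tidyr::pivot_longer(-dplyr::all_of(key_cols),
                        names_to = "sample_id", values_to = "count") |>
    dplyr::inner_join(sample_tissues, by = "sample_id")
  per_tissue <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(key_cols, "tissue")))) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     detection_rate = mean(.data$count > 0),
                     mean_count = mean(.data$count), .groups = "drop")
  summary <- per_tissue |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::summarise(min_mean = min(.data$mean_count),
                     mean_mean = mean(.data$mean_count),
                     max_mean = max(.data$mean_count), .groups = "drop")
  list(per_tissue = per_tissue, summary = summary)
}

#' Screen two exon sets for exactly identical exon sequences
#'
#' Reports every pair of exons (one from each set, after deduplication)
#' whose strand-aware nucleotide sequences are byte-identical. Exact matches
#' only; a single substitution breaks the pair.
#'
#' @param exons_a,exons_b Exon tibbles (`chrom`, `start`, `end`, `strand`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @return Tibble of identical pairs with both coordinate sets and the
#'   shared sequence length.
#' @export
exon_identity_screen <- function(exons_a, exons_b, genome) {
  one_seq <- function(e) {
    spliced_sequence(tibble::tibble(chrom = e$chrom, start = e$start,
                                    end = e$end, strand = e$strand,
                                    exon_rank = 1L), genome)
  }
  ua <- dplyr::distinct(exons_a[, c("chrom", "start", "end", "strand")])
  ub <- dplyr::distinct(exons_b[, c("chrom", "start", "end", "strand")])
  ua$seq <- vapply(seq_len(nrow(ua)), function(i) one_seq(ua[i, ]),
                   character(1))
  ub$seq <- vapply(seq_len(nrow(ub)), function(i) one_seq(ub[i, ]),
                   character(1))
  out <- dplyr::inner_join(
    dplyr::rename(ua, a_chrom = "chrom", a_start = "start", a_end = "end",
                  a_strand = "strand"),
    dplyr::rename(ub, b_chrom = "chrom", b_start = "start", b_end = "end",
                  b_strand = "strand"),
    by = "seq", relationship = "many-to-many")
  out$seq_length <- nchar(out$seq)
  dplyr::select(out, -"seq")
}

#' Tryptic digest of a protein
#'
#' Cleaves after K or R except when followed by P, with zero missed
#' cleavages.
#'
#' @param protein Amino-acid string.
#' @return Character vector of peptides in order.
#' @export
tryptic_peptides <- function(protein) {
  if (!nchar(protein)) return(character(0))
  cut <- gsub("(?<=[KR])(?!P)", "\r", protein, perl = TRUE)
  strsplit(cut, "\r", fixed = TRUE)[[1]]
}

#' Isoform-unique tryptic peptides
#'
#' Digests the isoform protein with trypsin (cleave after K/R, not before P,
#' zero missed cleavages), keeps peptides of at least `min_length` residues,
#' and returns those occurring as a substring of no background protein.
#'
#' @param protein Isoform amino-acid string.
#' @param background Character vector of background protein sequences (e.g.
#'   the canonical proteome the peptide must be absent from).
#' @param min_length Minimum peptide length (default 6).
#' @return Character vector of unique peptides (deduplicated, in order of
#'   first occurrence).
#' @export
unique_peptides <- function(protein, background, min_length = 6L) {
  peps <- tryptic_peptides(protein)
  peps <- unique(peps[nchar(peps) >= min_length])
  if (!length(peps)) return(character(0))
  in_bg <- vapply(peps, function(p) {
    any(vapply(background, function(b) grepl(p, b, fixed = TRUE),
               logical(1)))
  }, logical(1))
  peps[!in_bg]
}
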