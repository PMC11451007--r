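#' Configure a target/readthrough locus pair
#'
#' The readthrough (conjoined) gene splices exons of the target gene to exons
#' of a partner gene downstream; its transcripts overlap both loci, so
#' overlap with the partner locus disambiguates them from target-gene
#' transcripts.
#'
#' @param target_locus,partner_locus Region strings (see [parse_region()]) or
#'   single-row interval tibbles. Must share chrom and strand.
#' @param target_gene_id,partner_gene_id,readthrough_gene_id Gene labels used
#'   in outputs.
#' @return A `locus_config` list.
#' @export
locus_config <- function(target_locus, partner_locus,
                         target_gene_id = "TARGET",
                         partner_gene_id = "PARTNER",
                         readthrough_gene_id = "READTHROUGH") {
  if (is.character(target_locus)) target_locus <- parse_region(target_locus)
  if (is.character(partner_locus)) partner_locus <- parse_region(partner_locus)
  stopifnot(target_locus$chrom == partner_locus$chrom,
            target_locus$strand == partner_locus$strand)
  if (identical(target_locus, partner_locus)) {
    stop("target and partner loci must differ")
  }
  structure(list(target_locus = target_locus,
                 partner_locus = partner_locus,
                 target_gene_id = target_gene_id,
                 partner_gene_id = partner_gene_id,
                 readthrough_gene_id = readthrough_gene_id),
            class = "locus_config")
}

span_overlaps <- function(spans, locus) {
  spans$chrom == locus$chrom &
    (locus$strand == "*" | spans$strand == locus$strand) &
    spans$start <= locus$end & spans$end >= locus$start
}

#' Assign transcript calls to the target gene, the readthrough gene, or neither
#'
#' A call's genomic span (first to last exon) is intersected with the two
#' loci on the same strand. Spanning both loci (>= 1 bp each) labels it
#' `readthrough`; target-only overlap labels it `target`; anything else
#' (including partner-only overlap) is `neither` and excluded from both
#' genes' quantification.
#'
#' @param ts A [transcript_set()].
#' @param cfg A [locus_config()].
#' @param exonic_only If `TRUE`, require exonic (not just span) overlap.
#' @return The set with a `locus_label` column added to `ts$transcripts`.
#' @export
assign_to_locus <- function(ts, cfg, exonic_only = FALSE) {
  if (!n_calls(ts)) {
    ts$transcripts$locus_label <- character(0)
    return(ts)
  }
  if (exonic_only) {
    hit <- function(locus) {
      ov <- ts$exons$chrom == locus$chrom &
        (locus$strand == "*" | ts$exons$strand == locus$strand) &
        ts$exons$start <= locus$end & ts$exons$end >= locus$start
      keys <- unique(paste(ts$exons$sample_id, ts$exons$call_id,
                           sep = "\r")[ov])
      paste(ts$transcripts$sample_id, ts$transcripts$call_id,
            sep = "\r") %in% keys
    }
    in_target <- hit(cfg$target_locus)
    in_partner <- hit(cfg$partner_locus)
  } else {
    spans <- tx_spans(ts)
    i <- match(paste(ts$transcripts$sample_id, ts$transcripts$call_id),
               paste(spans$sample_id, spans$call_id))
    spans <- spans[i, ]
    in_target <- span_overlaps(spans, cfg$target_locus)
    in_partner <- span_overlaps(spans, cfg$partner_locus)
  }
  ts$transcripts$locus_label <- dplyr::case_when(
    in_target & in_partner ~ "readthrough",
    in_target ~ "target",
    TRUE ~ "neither")
  ts
}

#' Remove caller-artifact transcript calls
#'
#' Drops calls labeled `Genomic` at the transcript level and calls of genes
#' labeled `Antisense` or `Intergenic`; everything else (including `"other"`)
#' is retained.
#'
#' @param ts A [transcript_set()].
#' @return A filtered `transcript_set`; the number removed is available as
#'   `attr(, "n_removed")`.
#' @export
filter_artifacts <- function(ts) {
  keep <- !(ts$transcripts$caller_status == "Genomic" |
              ts$transcripts$gene_status %in% c("Antisense", "Intergenic"))
  out <- subset_calls(ts, ts$transcripts[keep, c("sample_id", "call_id")])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Gene length as the union of exonic bases, in kilobases
#'
#' The gene length used for RPK is the number of genomic bases covered by at
#' least one exon of any of the gene's transcripts (not the annotated span).
#'
#' @param exons Exon tibble (columns `chrom`, `start`, `end`) for one gene's
#'   transcripts.
#' @return Length in kb.
#' @export
gene_length_kb <- function(exons) {
  if (!nrow(exons)) stop("no exons supplied")
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(exons$start, exons$end)))
  sum(GenomicRanges::width(gr)) / 1000
}

#' Per-sample TPM from gene read counts
#'
#' For each sample: RPK = count / length_kb; scaling factor = sum(RPK) / 1e6;
#' TPM = RPK / scaling factor, so TPMs sum to one million within each sample.
#'
#' @param gene_counts Tibble with `sample_id`, `gene_id`, `read_count`,
#'   `gene_length_kb` covering all quantified genes per sample.
#' @return Tibble with added `rpk` and `tpm` columns.
#' @export
compute_tpm <- function(gene_counts) {
  stopifnot(all(c("sample_id", "gene_id", "read_count", "gene_length_kb")
                %in% names(gene_counts)))
  if (any(gene_counts$gene_length_kb <= 0)) stop("non-positive gene length")
  out <- gene_counts |>
    dplyr::mutate(rpk = .data$read_count / .data$gene_length_kb) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(tpm = .data$rpk / (sum(.data$rpk) / 1e6)) |>
    dplyr::ungroup()
  bad <- out |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(z = sum(.data$rpk) == 0, .groups = "drop")
  if (any(bad$z)) {
    stop("zero total RPK in sample(s): ",
         paste(bad$sample_id[bad$z], collapse = ", "))
  }
  out
}
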