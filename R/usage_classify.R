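#' Parameters for usage statistics and category calls
#' @param coding_min_aa Products shorter than this many amino acids are
#'   considered non-coding (default 150).
#' @param tissue_fold Tissue-specificity fold threshold (default 2).
#' @param min_occurrence Validity threshold in samples (default 3).
#' @return A `classify_params` list.
#' @export
classify_params <- function(coding_min_aa = 150L, tissue_fold = 2,
                            min_occurrence = 3L) {
  stopifnot(coding_min_aa > 0, tissue_fold > 0, min_occurrence > 0)
  structure(list(coding_min_aa = as.integer(coding_min_aa),
                 tissue_fold = tissue_fold,
                 min_occurrence = as.integer(min_occurrence)),
            class = "classify_params")
}

#' Per-sample transcript usage
#'
#' Usage of a merged transcript in a sample is its members' read counts
#' divided by the total read count of all the locus's merged transcripts in
#' that sample, so usages sum to 1 in every sample with locus expression.
#' Samples with zero locus counts are flagged in `attr(, "undefined_samples")`.
#'
#' @param merged A `merged_transcripts` object.
#' @return Long tibble with `composite_id`, `sample_id`, `usage`,
#'   `detected` (call present in the sample).
#' @export
usage_matrix <- function(merged) {
  m <- merged$members
  per_sample <- m |>
    dplyr::group_by(.data$composite_id, .data$sample_id) |>
    dplyr::summarise(reads = sum(.data$read_count), .groups = "drop")
  totals <- per_sample |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$reads), .groups = "drop")
  grid <- tidyr::expand_grid(composite_id = unique(merged$table$composite_id),
                             sample_id = totals$sample_id)
  um <- grid |>
    dplyr::left_join(per_sample, by = c("composite_id", "sample_id")) |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::mutate(detected = !is.na(.data$reads),
                  reads = dplyr::coalesce(.data$reads, 0),
                  usage = ifelse(.data$total > 0,
                                 .data$reads / .data$total, NA_real_)) |>
    dplyr::select("composite_id", "sample_id", "usage", "detected")
  attr(um, "undefined_samples") <- totals$sample_id[totals$total == 0]
  um
}

#' Median usage over detection-positive samples
#'
#' The median is computed over the samples in which the transcript is
#' detected with non-zero usage, matching how sparsely detected transcripts
#' are summarised.
#'
#' @param um Usage tibble from [usage_matrix()] (or [orf_usage()]; set
#'   `id_col = "orf_id"`).
#' @param id_col Name of the identifier column.
#' @return Tibble with the identifier column, `median_usage`, `n_detected`.
#' @export
median_usage <- function(um, id_col = "composite_id") {
  out <- um |>
    dplyr::filter(!is.na(.data$usage), .data$usage > 0) |>
    dplyr::group_by(.data[[id_col]]) |>
    dplyr::summarise(median_usage = stats::median(.data$usage),
                     n_detected = dplyr::n(), .groups = "drop")
  missing <- setdiff(unique(um[[id_col]]), out[[id_col]])
  if (length(missing)) {
    stop("transcript(s) never detected with non-zero usage: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  out
}

#' Per-ORF usage by summing transcripts sharing an ORF
#'
#' @param um Usage tibble from [usage_matrix()].
#' @param tx2orf Tibble mapping `composite_id` to `orf_id` (e.g. the merged
#'   table).
#' @return Long tibble with `orf_id`, `sample_id`, `usage`, `detected`;
#'   per sample the ORF usages sum to 1 where the locus is expressed.
#' @export
orf_usage <- function(um, tx2orf) {
  um |>
    dplyr::inner_join(tx2orf[, c("composite_id", "orf_id")],
                      by = "composite_id") |>
    dplyr::group_by(.data$orf_id, .data$sample_id) |>
    dplyr::summarise(usage = if (all(is.na(.data$usage))) NA_real_
                     else sum(.data$usage, na.rm = TRUE),
                     detected = any(.data$detected), .groups = "drop")
}

#' Flag tissue-specific transcripts
#'
#' A transcript is specific to tissue T when its mean usage across T's
#' samples is positive and at least `tissue_fold` times its mean usage in
#' every other tissue (inclusive threshold; a transcript expressed in a
#' single tissue only is specific to it).
#'
#' @param um Usage tibble from [usage_matrix()].
#' @param sample_tissues Tibble with `sample_id`, `tissue`.
#' @param params A [classify_params()].
#' @return Tibble with `composite_id`, `specific_tissue` (`NA` when not
#'   tissue-specific) plus the per-tissue mean usages in `attr(, "tissue_means")`.
#' @export
tissue_specific <- function(um, sample_tissues, params = classify_params()) {
  tissues <- unique(sample_tissues$tissue)
  ids <- unique(um$composite_id)
  if (length(tissues) < 2) {
    warning("fewer than two tissues; no transcript flagged tissue-specific")
    return(tibble::tibble(composite_id = ids,
                          specific_tissue = NA_character_))
  }
  means <- um |>
    dplyr::inner_join(sample_tissues, by = "sample_id") |>
    dplyr::filter(!is.na(.data$usage)) |>
    dplyr::group_by(.data$composite_id, .data$tissue) |>
    dplyr::summarise(mean_usage = mean(.data$usage), .groups = "drop")
  flags <- means |>
    dplyr::group_by(.data$composite_id) |>
    dplyr::summarise(specific_tissue = {
      m <- .data$mean_usage
      names(m) <- .data$tissue
      best <- which.max(m)
      others <- m[-best]
      if (m[best] > 0 &&
          (length(others) == 0 ||
             all(m[best] >= params$tissue_fold * others))) {
        names(m)[best]
      } else NA_character_
    }, .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(composite_id = ids), flags,
                          by = "composite_id")
  attr(out, "tissue_means") <- means
  out
}

utr_matches_ref <- function(sig, distal, ref_sig, ref_distal, tol) {
  if (sig == "" && is.na(distal)) return(TRUE)  # empty UTR: trivially known
  any(ref_sig == sig & !is.na(ref_distal) &
        abs(ref_distal - distal) <= tol)
}

#' Novelty of merged transcripts, their ORFs and UTRs versus a reference
#'
#' The reference annotation is processed through the same ORF/UTR engine.
#' An ORF is known iff its genomic CDS block set equals a reference ORF's;
#' a UTR is known iff a reference UTR has identical internal boundaries and
#' a distal end within the merge tolerance; a transcript is known iff a
#' single reference transcript matches it under all three merge criteria.
#'
#' @param merged A `merged_transcripts` object.
#' @param anno Call-level annotation tibble the merge was built from.
#' @param ref_anno Annotation tibble for the reference models (from
#'   [annotate_transcripts()] on the reference set).
#' @param mparams A [merge_params()] (supplies the end tolerance).
#' @return `merged$table` with logical columns `orf_known`, `utr5_known`,
#'   `utr3_known`, `tx_known` appended.
#' @export
novelty_flags <- function(merged, anno, ref_anno,
                          mparams = merge_params()) {
  tab <- merged$table
  rep_anno <- anno[match(paste(tab$rep_sample_id, tab$rep_call_id),
                         paste(anno$sample_id, anno$call_id)), ]
  tol <- mparams$end_tolerance
  if (is.null(ref_anno) || !nrow(ref_anno)) {
    warning("empty reference: all transcripts, ORFs and UTRs called novel")
    tab$orf_known <- FALSE
    tab$utr5_known <- FALSE
    tab$utr3_known <- FALSE
    tab$tx_known <- FALSE
    return(tab)
  }
  ref_orfs <- ref_anno$orf_sig[ref_anno$has_orf]
  n <- nrow(tab)
  orf_known <- logical(n); u5 <- logical(n); u3 <- logical(n)
  txk <- logical(n)
  for (i in seq_len(n)) {
    a <- rep_anno[i, ]
    orf_known[i] <- a$has_orf && a$orf_sig %in% ref_orfs
    u5[i] <- utr_matches_ref(a$utr5_sig, a$utr5_distal,
                             ref_anno$utr5_sig, ref_anno$utr5_distal, tol)
    u3[i] <- utr_matches_ref(a$utr3_sig, a$utr3_distal,
                             ref_anno$utr3_sig, ref_anno$utr3_distal, tol)
    same_ref <- ref_anno$orf_sig == a$orf_sig &
      ref_anno$utr5_sig == a$utr5_sig &
      ref_anno$utr3_sig == a$utr3_sig &
      (is.na(a$utr5_distal) |
         abs(ref_anno$utr5_distal - a$utr5_distal) <= tol) &
      (is.na(a$utr3_distal) |
         abs(ref_anno$utr3_distal - a$utr3_distal) <= tol)
    txk[i] <- any(same_ref, na.rm = TRUE)
  }
  tab$orf_known <- orf_known
  tab$utr5_known <- u5
  tab$utr3_known <- u3
  tab$tx_known <- txk
  tab
}

#' The eight-way novelty/coding/NMD category cascade
#'
#' Categories are assigned in strict precedence: NMD-positive transcripts
#' first (split by transcript novelty), then non-coding transcripts (no ORF
#' or product below `coding_min_aa`, split by novelty), then known coding
#' transcripts, and finally novel coding transcripts split by ORF/UTR
#' novelty. The cascade is total: every transcript receives exactly one
#' category.
#'
#' @param nmd,has_orf,tx_known,orf_known,utr5_known,utr3_known Logical
#'   vectors.
#' @param protein_length Integer vector (NA where no ORF).
#' @param params A [classify_params()].
#' @return Character vector of categories.
#' @export
classify_category <- function(nmd, has_orf, protein_length, tx_known,
                              orf_known, utr5_known, utr3_known,
                              params = classify_params()) {
  noncoding <- !has_orf | (!is.na(protein_length) &
                             protein_length < params$coding_min_aa)
  utr_novel <- !utr5_known | !utr3_known
  dplyr::case_when(
    nmd & tx_known ~ "NMD_Known",
    nmd ~ "NMD_Novel",
    noncoding & tx_known ~ "Non_coding_Known",
    noncoding ~ "Non_coding_Novel",
    tx_known ~ "Coding_Known",
    orf_known & utr_novel ~ "Novel_3/5UTR_only",
    orf_known ~ "Novel_combination",
    utr_novel ~ "Novel_ORF_and_UTR",
    TRUE ~ "Novel_ORF_only")
}

#' Classify merged transcripts against a reference annotation
#'
#' Convenience wrapper: computes novelty flags ([novelty_flags()]), pulls
#' NMD status and protein length from the representative call, and applies
#' the category cascade ([classify_category()]).
#'
#' @inheritParams novelty_flags
#' @param params A [classify_params()].
#' @return `merged$table` with novelty flags, `nmd`, `protein_length`,
#'   `orf_sig` and `category` columns.
#' @export
classify_transcripts <- function(merged, anno, ref_anno,
                                 params = classify_params(),
                                 mparams = merge_params()) {
  tab <- novelty_flags(merged, anno, ref_anno, mparams)
  rep_anno <- anno[match(paste(tab$rep_sample_id, tab$rep_call_id),
                         paste(anno$sample_id, anno$call_id)), ]
  tab$nmd <- rep_anno$nmd
  tab$has_orf <- rep_anno$has_orf
  tab$protein_length <- rep_anno$protein_length
  tab$orf_sig <- rep_anno$orf_sig
  tab$category <- classify_category(tab$nmd, tab$has_orf, tab$protein_length,
                                    tab$tx_known, tab$orf_known,
                                    tab$utr5_known, tab$utr3_known, params)
  tab
}
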