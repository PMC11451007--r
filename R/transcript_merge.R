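#' Parameters for cross-sample transcript merging
#' @param end_tolerance Maximum distance (bp, inclusive) between a UTR's
#'   distal end and its cluster anchor's distal end.
#' @return A `merge_params` list.
#' @export
merge_params <- function(end_tolerance = 20L) {
  stopifnot(end_tolerance >= 0)
  structure(list(end_tolerance = as.integer(end_tolerance)),
            class = "merge_params")
}

#' Cluster UTR records with positional end tolerance
#'
#' Two records share a UTR ID iff their internal boundaries are identical
#' and their distal ends lie within `end_tolerance` of the cluster anchor's
#' distal end. Anchors are chosen greedily from records ordered by read
#' support, then coordinate, which keeps every cluster's diameter bounded
#' (20-bp steps cannot chain into larger drifts) and makes the clustering
#' deterministic under permutation of the input. Records with an empty UTR
#' form the single class `"{side}UTR_0"`.
#'
#' @param records Tibble with columns `internal_sig`, `distal_end` and
#'   `support` (read counts; `NA` treated as 0). One row per transcript call.
#' @param side `"5"` or `"3"`.
#' @param params A [merge_params()].
#' @return `records` with a `utr_id` column appended.
#' @export
cluster_utrs <- function(records, side = c("5", "3"), params = merge_params()) {
  side <- match.arg(side)
  stopifnot(all(c("internal_sig", "distal_end") %in% names(records)))
  n <- nrow(records)
  records$utr_id <- rep(NA_character_, n)
  if (!n) return(records)
  support <- if ("support" %in% names(records)) records$support else rep(0, n)
  support[is.na(support)] <- 0
  empty <- records$internal_sig == "" & is.na(records$distal_end)
  records$utr_id[empty] <- paste0(side, "UTR_0")
  idx <- which(!empty)
  if (!length(idx)) return(records)
  ord <- idx[order(records$internal_sig[idx], -support[idx],
                   records$distal_end[idx])]
  anchor_sig <- character(0)
  anchor_pos <- numeric(0)
  assign_cluster <- integer(length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    hit <- which(anchor_sig == records$internal_sig[i] &
                   abs(anchor_pos - records$distal_end[i]) <=
                     params$end_tolerance)
    if (length(hit)) {
      assign_cluster[k] <- hit[1]
    } else {
      anchor_sig <- c(anchor_sig, records$internal_sig[i])
      anchor_pos <- c(anchor_pos, records$distal_end[i])
      assign_cluster[k] <- length(anchor_sig)
    }
  }
  records$utr_id[ord] <- paste0(side, "UTR_", assign_cluster)
  records
}

#' Merge per-sample transcript calls into named cross-sample transcripts
#'
#' Calls sharing the exact (ORF ID, 5'UTR ID, 3'UTR ID) triple collapse into
#' one merged transcript named `"{orf_id}_{utr5_id}_{utr3_id}"`. The
#' representative exon chain is the member call with the highest read count.
#'
#' @param anno Annotation tibble (from [annotate_transcripts()]) carrying
#'   `orf_id`, `utr5_id`, `utr3_id` and `read_count` columns.
#' @param ts The [transcript_set()] the annotations came from.
#' @return A `merged_transcripts` object: `$table` (one row per merged
#'   transcript: `composite_id`, the ID triple, `occurrence`, `n_calls`,
#'   total read count, representative call key), `$members` (call-level
#'   membership), `$representatives` (a `transcript_set` of representative
#'   models).
#' @export
merge_calls <- function(anno, ts) {
  need <- c("orf_id", "utr5_id", "utr3_id")
  missing_ids <- !stats::complete.cases(anno[, need])
  if (any(missing_ids)) {
    stop("calls lack merge IDs: ",
         paste(utils::head(anno$call_id[missing_ids], 5), collapse = ", "))
  }
  anno$read_count[is.na(anno$read_count)] <- 0
  tab <- anno |>
    dplyr::mutate(composite_id = paste(.data$orf_id, .data$utr5_id,
                                       .data$utr3_id, sep = "_")) |>
    dplyr::group_by(.data$composite_id, .data$orf_id, .data$utr5_id,
                    .data$utr3_id) |>
    dplyr::arrange(dplyr::desc(.data$read_count), .data$sample_id,
                   .data$call_id, .by_group = TRUE) |>
    dplyr::summarise(occurrence = dplyr::n_distinct(.data$sample_id),
                     n_calls = dplyr::n(),
                     total_reads = sum(.data$read_count),
                     rep_sample_id = .data$sample_id[1],
                     rep_call_id = .data$call_id[1],
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$occurrence),
                   dplyr::desc(.data$total_reads), .data$composite_id)
  members <- anno |>
    dplyr::mutate(composite_id = paste(.data$orf_id, .data$utr5_id,
                                       .data$utr3_id, sep = "_")) |>
    dplyr::select("composite_id", "sample_id", "call_id", "read_count")
  reps <- subset_calls(ts, tibble::tibble(sample_id = tab$rep_sample_id,
                                          call_id = tab$rep_call_id))
  structure(list(table = tab, members = members, representatives = reps),
            class = "merged_transcripts")
}

#' @export
print.merged_transcripts <- function(x, ...) {
  cat("<merged_transcripts> ", nrow(x$table), " merged transcript(s) from ",
      nrow(x$members), " call(s)\n", sep = "")
  invisible(x)
}

subset_merged <- function(merged, keep_ids) {
  keep <- merged$table$composite_id %in% keep_ids
  tab <- merged$table[keep, ]
  members <- merged$members[merged$members$composite_id %in% keep_ids, ]
  reps <- if (nrow(tab)) {
    subset_calls(merged$representatives,
                 tibble::tibble(sample_id = tab$rep_sample_id,
                                call_id = tab$rep_call_id))
  } else {
    transcript_set(merged$representatives$transcripts[0, ],
                   merged$representatives$exons[0, ])
  }
  structure(list(table = tab, members = members, representatives = reps),
            class = "merged_transcripts")
}

#' Split merged transcripts into valid and sub-threshold sets
#'
#' Transcripts detected in at least `min_occurrence` samples are valid; the
#' rest are retained for reporting (sub-threshold transcripts are not
#' silently dropped).
#'
#' @param merged A `merged_transcripts` object from [merge_calls()].
#' @param min_occurrence Minimum number of distinct samples (default 3).
#' @return List with `valid` and `discarded` `merged_transcripts`.
#' @export
filter_valid <- function(merged, min_occurrence = 3L) {
  ok <- merged$table$occurrence >= min_occurrence
  list(valid = subset_merged(merged, merged$table$composite_id[ok]),
       discarded = subset_merged(merged, merged$table$composite_id[!ok]))
}
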