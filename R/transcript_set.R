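#' @import tibble
#' @importFrom rlang .data
NULL

#' Construct a set of transcript calls
#'
#' A `transcript_set` is the package's shared container for per-sample
#' transcript models: one row per transcript call plus an exon table holding
#' each call's exon chain in 5'-to-3' transcript orientation. All genomic
#' coordinates are 1-based inclusive.
#'
#' @param transcripts Tibble with columns `sample_id`, `call_id`,
#'   `gene_label`, `caller_status`, `gene_status`, `read_count`. Missing
#'   status columns are filled with `"other"`; missing `read_count` with `NA`.
#' @param exons Tibble with columns `sample_id`, `call_id`, `exon_rank`
#'   (1 = 5'-most exon), `chrom`, `start`, `end`, `strand`.
#' @return An object of class `transcript_set`.
#' @export
transcript_set <- function(transcripts, exons) {
  transcripts <- tibble::as_tibble(transcripts)
  exons <- tibble::as_tibble(exons)
  if (!"gene_label" %in% names(transcripts)) transcripts$gene_label <- NA_character_
  if (!"caller_status" %in% names(transcripts)) transcripts$caller_status <- "other"
  if (!"gene_status" %in% names(transcripts)) transcripts$gene_status <- "other"
  if (!"read_count" %in% names(transcripts)) transcripts$read_count <- NA_real_
  transcripts$caller_status[is.na(transcripts$caller_status)] <- "other"
  transcripts$gene_status[is.na(transcripts$gene_status)] <- "other"
  ts <- structure(list(transcripts = transcripts, exons = exons),
                  class = "transcript_set")
  validate_transcript_set(ts)
  ts
}

validate_transcript_set <- function(ts) {
  tx <- ts$transcripts
  ex <- ts$exons
  need_tx <- c("sample_id", "call_id", "gene_label", "caller_status",
               "gene_status", "read_count")
  need_ex <- c("sample_id", "call_id", "exon_rank", "chrom", "start", "end",
               "strand")
  stopifnot(all(need_tx %in% names(tx)), all(need_ex %in% names(ex)))
  if (anyDuplicated(tx[, c("sample_id", "call_id")])) {
    stop("duplicate (sample_id, call_id) in transcript table")
  }
  if (any(!is.na(tx$read_count) & tx$read_count < 0)) {
    stop("negative read_count")
  }
  if (nrow(ex)) {
    if (any(ex$end < ex$start)) stop("exon with end < start")
    if (!all(ex$strand %in% c("+", "-"))) stop("exon strand must be '+' or '-'")
    bad <- ex |>
      dplyr::arrange(.data$sample_id, .data$call_id, .data$exon_rank) |>
      dplyr::group_by(.data$sample_id, .data$call_id) |>
      dplyr::summarise(
        ok = exon_chain_ok(.data$start, .data$end, .data$strand,
                           .data$chrom, .data$exon_rank),
        .groups = "drop"
      )
    if (any(!bad$ok)) {
      who <- bad[!bad$ok, ]
      stop("invalid exon chain for ", who$sample_id[1], "/", who$call_id[1])
    }
    orphan <- !paste(ex$sample_id, ex$call_id) %in% paste(tx$sample_id, tx$call_id)
    if (any(orphan)) stop("exon without parent transcript: ",
                          ex$call_id[orphan][1])
  }
  invisible(ts)
}

# One chain: same chrom/strand, ranks 1..n, pairwise non-overlapping,
# genomic coordinates increasing (+) or decreasing (-) along the chain,
# introns >= 1 bp.
exon_chain_ok <- function(start, end, strand, chrom, rank) {
  n <- length(start)
  if (length(unique(chrom)) != 1L || length(unique(strand)) != 1L) return(FALSE)
  if (!identical(sort(rank), seq_len(n))) return(FALSE)
  o <- order(rank)
  start <- start[o]; end <- end[o]
  if (n == 1L) return(TRUE)
  if (strand[1] == "+") {
    all(start[-1] - end[-n] >= 2L)
  } else {
    all(start[-n] - end[-1] >= 2L)
  }
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("<transcript_set> ", nrow(x$transcripts), " transcript call(s), ",
      nrow(x$exons), " exon(s), ",
      length(unique(x$transcripts$sample_id)), " sample(s)\n", sep = "")
  invisible(x)
}

#' Number of transcript calls in a set
#' @param ts A `transcript_set`.
#' @return Integer count.
#' @export
n_calls <- function(ts) nrow(ts$transcripts)

#' Genomic span of each transcript call
#'
#' The span is the first-to-last-exon genomic interval of each call.
#'
#' @param ts A `transcript_set`.
#' @return Tibble with `sample_id`, `call_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
tx_spans <- function(ts) {
  ts$exons |>
    dplyr::group_by(.data$sample_id, .data$call_id) |>
    dplyr::summarise(chrom = .data$chrom[1],
                     start = min(.data$start),
                     end = max(.data$end),
                     strand = .data$strand[1],
                     .groups = "drop")
}

#' Subset a transcript set by call keys
#' @param ts A `transcript_set`.
#' @param keys Tibble with `sample_id` and `call_id` columns.
#' @return A `transcript_set` restricted to the given calls.
#' @export
subset_calls <- function(ts, keys) {
  k <- paste(keys$sample_id, keys$call_id, sep = "\r")
  tx <- ts$transcripts[paste(ts$transcripts$sample_id,
                             ts$transcripts$call_id, sep = "\r") %in% k, ]
  ex <- ts$exons[paste(ts$exons$sample_id,
                       ts$exons$call_id, sep = "\r") %in% k, ]
  transcript_set(tx, ex)
}

#' Combine transcript sets
#' @param ... `transcript_set` objects.
#' @return A single combined `transcript_set`.
#' @export
bind_transcript_sets <- function(...) {
  sets <- list(...)
  transcript_set(dplyr::bind_rows(lapply(sets, `[[`, "transcripts")),
                 dplyr::bind_rows(lapply(sets, `[[`, "exons")))
}

#' Exon chain of one transcript call
#' @param ts A `transcript_set`.
#' @param sample_id,call_id Call key.
#' @return Tibble of exons ordered 5' to 3'.
#' @export
exon_chain <- function(ts, sample_id, call_id) {
  ex <- ts$exons[ts$exons$sample_id == sample_id &
                 ts$exons$call_id == call_id, ]
  if (!nrow(ex)) stop("no such call: ", sample_id, "/", call_id)
  ex[order(ex$exon_rank), ]
}
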