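#' Parse a printed locus string
#'
#' Accepts the compact form used for printed loci, e.g.
#' `"chr16:28,474,111-28,495,575:-"`. Thousands separators are ignored; the
#' strand suffix is optional (defaults to `"*"`).
#'
#' @param x Character scalar.
#' @return Tibble with `chrom`, `start`, `end`, `strand` (1-based inclusive).
#' @export
parse_region <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x2 <- gsub(",", "", x)
  m <- regmatches(x2, regexec("^([^:]+):([0-9]+)[-_]([0-9]+)(:([+*-]))?$", x2))[[1]]
  if (!length(m)) stop("cannot parse region: ", x)
  tibble::tibble(chrom = m[2],
                 start = as.integer(m[3]),
                 end = as.integer(m[4]),
                 strand = ifelse(m[6] == "", "*", m[6]))
}

#' Length of genomic intervals in base pairs
#'
#' With 1-based inclusive coordinates the length is `end - start + 1`; a
#' single-base interval has length 1.
#'
#' @param x Tibble with `start` and `end` columns (e.g. from
#'   [parse_region()]), or a region string.
#' @return Integer vector of lengths.
#' @export
interval_length <- function(x) {
  if (is.character(x)) x <- parse_region(x)
  stopifnot(all(x$end >= x$start))
  as.integer(x$end - x$start + 1L)
}

gtf_attr <- function(meta, key) {
  if (key %in% names(meta)) as.character(meta[[key]]) else rep(NA_character_, nrow(meta))
}

#' Read transcript models from a GTF file
#'
#' Imports `transcript` and `exon` features through rtracklayer and builds a
#' [transcript_set()]. Exon chains are ordered 5' to 3' in transcript
#' orientation (for minus-strand transcripts, genomic coordinates decrease
#' along the chain). Caller novelty labels are read from TALON-style
#' attributes and default to `"other"` when absent (the usual case for
#' reference-dialect annotation).
#'
#' @param path GTF file path.
#' @param dialect `"caller"` for per-sample caller output, `"reference"` for
#'   a reference annotation. Both are parsed identically; the dialect fixes
#'   the default `sample_id`.
#' @param sample_id Sample label stored on every call; defaults to the file
#'   name without extension (caller dialect) or `"reference"`.
#' @param status_attrs Named character vector giving the attribute keys that
#'   carry the transcript-level and gene-level novelty labels.
#' @return A [transcript_set()].
#' @export
read_gtf <- function(path, dialect = c("caller", "reference"),
                     sample_id = NULL,
                     status_attrs = c(transcript = "transcript_status",
                                      gene = "gene_status")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample_id)) {
    sample_id <- if (dialect == "reference") "reference"
                 else sub("\\.[^.]*$", "", basename(path))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("malformed GTF '", path, "': ",
                                          conditionMessage(e)))
  meta <- as.data.frame(S4Vectors::mcols(gr))
  if (!all(c("type", "transcript_id") %in% names(meta))) {
    stop("GTF lacks type/transcript_id attributes: ", path)
  }
  is_tx <- meta$type == "transcript"
  is_ex <- meta$type == "exon"
  if (!any(is_ex)) stop("GTF has no exon features: ", path)
  ex_id <- meta$transcript_id[is_ex]
  tx_id <- meta$transcript_id[is_tx]
  if (!all(ex_id %in% tx_id)) {
    stop("exon without parent transcript feature: ",
         setdiff(ex_id, tx_id)[1])
  }
  tstat <- gtf_attr(meta, status_attrs[["transcript"]])[is_tx]
  gstat <- gtf_attr(meta, status_attrs[["gene"]])[is_tx]
  tstat[is.na(tstat)] <- "other"
  gstat[is.na(gstat)] <- "other"
  transcripts <- tibble::tibble(
    sample_id = sample_id,
    call_id = tx_id,
    gene_label = gtf_attr(meta, "gene_id")[is_tx],
    caller_status = tstat,
    gene_status = gstat,
    read_count = NA_real_
  )
  exg <- gr[is_ex]
  ex <- tibble::tibble(
    sample_id = sample_id,
    call_id = ex_id,
    chrom = as.character(GenomicRanges::seqnames(exg)),
    start = GenomicRanges::start(exg),
    end = GenomicRanges::end(exg),
    strand = as.character(GenomicRanges::strand(exg))
  )
  ex <- ex |>
    dplyr::group_by(.data$call_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(exon_rank = if (.data$strand[1] == "-")
      rev(seq_len(dplyr::n())) else seq_len(dplyr::n())) |>
    dplyr::ungroup()
  transcript_set(transcripts, ex)
}

#' Write a transcript set (or merged transcripts) to GTF
#'
#' @param x A [transcript_set()], or a merged-transcript table with a
#'   `composite_id` column plus a `transcript_set` of representative models
#'   (see [merge_calls()]); composite IDs are written as `transcript_id`.
#' @param path Output path.
#' @param source GTF source column.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(x, path, source = "isocollapse") {
  if (inherits(x, "merged_transcripts")) {
    ts <- x$representatives
    id_map <- stats::setNames(x$table$composite_id,
                              paste(x$table$rep_sample_id, x$table$rep_call_id,
                                    sep = "\r"))
    ts$transcripts$call_id_out <-
      id_map[paste(ts$transcripts$sample_id, ts$transcripts$call_id, sep = "\r")]
    ts$exons$call_id_out <-
      id_map[paste(ts$exons$sample_id, ts$exons$call_id, sep = "\r")]
  } else {
    ts <- x
    ts$transcripts$call_id_out <- ts$transcripts$call_id
    ts$exons$call_id_out <- ts$exons$call_id
  }
  if (!n_calls(ts)) stop("refusing to write an empty transcript set")
  tx <- ts$transcripts
  sp <- tx_spans(ts)
  tx <- dplyr::left_join(tx, sp, by = c("sample_id", "call_id"))
  attr_str <- function(gene, id, tstat, gstat) {
    sprintf('gene_id "%s"; transcript_id "%s"; transcript_status "%s"; gene_status "%s";',
            gene, id, tstat, gstat)
  }
  tx_lines <- sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                      tx$chrom, source, tx$start, tx$end, tx$strand,
                      attr_str(tx$gene_label, tx$call_id_out,
                               tx$caller_status, tx$gene_status))
  ex <- dplyr::left_join(
    ts$exons,
    tx[, c("sample_id", "call_id", "gene_label", "caller_status", "gene_status")],
    by = c("sample_id", "call_id"))
  ex_lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                      ex$chrom, source, ex$start, ex$end, ex$strand,
                      attr_str(ex$gene_label, ex$call_id_out,
                               ex$caller_status, ex$gene_status))
  # keep each transcript line followed by its exons, in call order
  ord <- order(match(paste(ex$sample_id, ex$call_id),
                     paste(tx$sample_id, tx$call_id)), ex$exon_rank)
  out <- character(0)
  ex_by_tx <- split(ex_lines[ord],
                    factor(paste(ex$sample_id, ex$call_id)[ord],
                           levels = paste(tx$sample_id, tx$call_id)))
  for (i in seq_len(nrow(tx))) out <- c(out, tx_lines[i], ex_by_tx[[i]])
  writeLines(out, path)
  invisible(path)
}

#' Read a transcript quantification table
#'
#' Expects a TSV with header columns `sample_id`, `transcript_id`,
#' `read_count`. Transcripts absent from the table stay absent (they are not
#' zero-filled).
#'
#' @param path TSV path.
#' @return Tibble with `sample_id`, `call_id`, `read_count`.
#' @export
read_quant <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "transcript_id", "read_count")
  if (!all(need %in% names(d))) {
    stop("quantification TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(is.na(d$read_count)) || any(d$read_count < 0)) {
    stop("read counts must be non-negative numbers")
  }
  if (anyDuplicated(d[, c("sample_id", "transcript_id")])) {
    stop("duplicate (sample_id, transcript_id) row in ", path)
  }
  tibble::tibble(sample_id = as.character(d$sample_id),
                 call_id = as.character(d$transcript_id),
                 read_count = as.numeric(d$read_count))
}

#' Attach read counts from a quantification table to a transcript set
#' @param ts A [transcript_set()].
#' @param quant Tibble from [read_quant()].
#' @return The set with `read_count` filled where the table has entries.
#' @export
attach_counts <- function(ts, quant) {
  i <- match(paste(ts$transcripts$sample_id, ts$transcripts$call_id),
             paste(quant$sample_id, quant$call_id))
  hit <- !is.na(i)
  ts$transcripts$read_count[hit] <- quant$read_count[i[hit]]
  ts
}

#' Read TSS peaks or polyA-site clusters from BED
#'
#' BED half-open 0-based records are converted to the package's 1-based
#' inclusive convention (via rtracklayer). A missing strand column (or `"."`)
#' yields strand `"*"`, treated as strand-agnostic in later comparisons.
#'
#' @param path BED3+ file.
#' @param kind `"tss"` or `"pas"` (recorded on the result).
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `kind`.
#' @export
read_bed_intervals <- function(path, kind = c("tss", "pas")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(utils::read.table(path, sep = "\t", header = FALSE,
                                    stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(raw)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          kind = character()))
  }
  if (any(raw[[3]] <= raw[[2]])) stop("BED record with end <= start in ", path)
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr),
                 strand = as.character(GenomicRanges::strand(gr)),
                 kind = kind)
}

#' Write intervals back to BED
#' @param intervals Tibble with `chrom`, `start`, `end`, `strand` (1-based
#'   inclusive; converted to BED convention on write).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed_intervals <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start, intervals$end),
    strand = intervals$strand)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a splice-junction table
#'
#' Junctions are intron intervals (first to last intronic base, 1-based
#' inclusive) with strand. Any additional columns are treated as per-sample
#' read counts.
#'
#' @param path TSV with header `chrom`, `intron_start`, `intron_end`,
#'   `strand`, then optional per-sample count columns.
#' @return Tibble; count columns (if any) retain their sample names.
#' @export
read_junctions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "intron_start", "intron_end", "strand")
  if (!all(need %in% names(d))) {
    stop("junction TSV must start with columns: ", paste(need, collapse = ", "))
  }
  d <- d[!duplicated(d[, need]), , drop = FALSE]
  tibble::as_tibble(d)
}

#' Load a genome FASTA
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet] named by the first token of each
#'   header.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Spliced sequence of an exon chain
#'
#' Concatenates exon sequences in 5'-to-3' transcript order; minus-strand
#' exons are reverse-complemented. The result length equals the summed exon
#' lengths.
#'
#' @param exons Tibble of one exon chain (columns `chrom`, `start`, `end`,
#'   `strand`, `exon_rank`), e.g. from [exon_chain()].
#' @param genome A named [Biostrings::DNAStringSet].
#' @return Character scalar nucleotide sequence.
#' @export
spliced_sequence <- function(exons, genome) {
  exons <- exons[order(exons$exon_rank), ]
  chrom <- exons$chrom[1]
  if (!chrom %in% names(genome)) stop("contig not in genome: ", chrom)
  clen <- length(genome[[chrom]])
  if (any(exons$end > clen) || any(exons$start < 1)) {
    stop("exon beyond contig bounds on ", chrom)
  }
  pieces <- Biostrings::extractAt(genome[[chrom]],
                                  IRanges::IRanges(exons$start, exons$end))
  if (exons$strand[1] == "-") pieces <- Biostrings::reverseComplement(pieces)
  paste(as.character(pieces), collapse = "")
}
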