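#' Run the full locus-centric isoform analysis
#'
#' Orchestrates the stages end to end: read per-sample transcript models and
#' counts, assign calls to the target or readthrough locus, drop caller
#' artifacts, quantify genes (TPM), predict ORFs/UTRs/NMD, merge calls
#' across samples into named transcripts, apply the validity filter,
#' compute usage and tissue specificity, classify novelty categories
#' against the reference annotation, and corroborate transcript ends and
#' junctions against the reference atlases.
#'
#' @param gtf Character vector of per-sample GTF paths, or a
#'   [transcript_set()] already holding all calls.
#' @param quant Character vector of quantification TSV paths, a single
#'   path, or a tibble from [read_quant()]. Ignored when `gtf` is a
#'   `transcript_set` with read counts filled.
#' @param genome FASTA path or named [Biostrings::DNAStringSet].
#' @param ref_gtf Reference annotation GTF path or `transcript_set`.
#' @param locus A [locus_config()].
#' @param tss,pas BED paths or interval tibbles ([read_bed_intervals()]);
#'   optional.
#' @param junctions Junction TSV path or tibble ([read_junctions()]);
#'   optional. Extra columns are treated as per-sample counts and feed
#'   [junction_detection_rates()] when `samples` is given.
#' @param samples Sample-to-tissue TSV path or tibble (`sample_id`,
#'   `tissue`); optional.
#' @param out_dir Optional output directory for the stage TSV/GTF files.
#' @param orf_params,mparams,cparams,vparams Stage parameter objects; the
#'   defaults are the standard settings (20-bp end tolerance, 50-nt NMD
#'   rule, 150-aa coding threshold, 2x tissue rule, >= 3-sample validity,
#'   50-bp end tolerances).
#' @return An `isocollapse_result` list with the per-stage tables and a
#'   `summary` of headline numbers.
#' @export
run_pipeline <- function(gtf, quant = NULL, genome, ref_gtf, locus,
                         tss = NULL, pas = NULL, junctions = NULL,
                         samples = NULL, out_dir = NULL,
                         orf_params = isocollapse::orf_params(),
                         mparams = merge_params(),
                         cparams = classify_params(),
                         vparams = validation_params()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  # ---- inputs -------------------------------------------------------------
  calls <- stage("read_calls", {
    if (inherits(gtf, "transcript_set")) gtf
    else do.call(bind_transcript_sets, lapply(gtf, read_gtf, dialect = "caller"))
  })
  if (!is.null(quant)) {
    q <- stage("read_quant", {
      if (is.character(quant)) dplyr::bind_rows(lapply(quant, read_quant))
      else quant
    })
    calls <- attach_counts(calls, q)
  }
  genome <- stage("read_genome", {
    if (is.character(genome)) read_genome(genome) else genome
  })
  reference <- stage("read_reference", {
    if (is.character(ref_gtf)) read_gtf(ref_gtf, dialect = "reference")
    else ref_gtf
  })
  load_iv <- function(x, kind) {
    if (is.null(x)) NULL
    else if (is.character(x)) read_bed_intervals(x, kind)
    else x
  }
  tss <- stage("read_tss", load_iv(tss, "tss"))
  pas <- stage("read_pas", load_iv(pas, "pas"))
  junctions <- stage("read_junctions", {
    if (is.character(junctions)) read_junctions(junctions) else junctions
  })
  samples <- stage("read_samples", {
    if (is.character(samples)) {
      tibble::as_tibble(utils::read.delim(samples, stringsAsFactors = FALSE))
    } else samples
  })

  # ---- locus assignment and artifact filter -------------------------------
  n_in <- n_calls(calls)
  calls <- stage("assign_to_locus", assign_to_locus(calls, locus))
  label_counts <- table(calls$transcripts$locus_label)
  kept <- stage("filter_artifacts", filter_artifacts(calls))
  n_artifacts <- attr(kept, "n_removed")

  # ---- gene-level quantification ------------------------------------------
  gene_quant <- stage("gene_quant", {
    tx <- kept$transcripts
    tx$gene_id <- dplyr::case_when(
      tx$locus_label == "target" ~ locus$target_gene_id,
      tx$locus_label == "readthrough" ~ locus$readthrough_gene_id,
      TRUE ~ NA_character_)
    tx <- tx[!is.na(tx$gene_id), ]
    if (!nrow(tx)) {
      tibble::tibble(sample_id = character(), gene_id = character(),
                     read_count = numeric(), gene_length_kb = numeric(),
                     rpk = numeric(), tpm = numeric())
    } else {
      lens <- tx |>
        dplyr::distinct(.data$gene_id) |>
        dplyr::mutate(gene_length_kb = vapply(.data$gene_id, function(g) {
          k <- tx[tx$gene_id == g, c("sample_id", "call_id")]
          ex <- kept$exons[paste(kept$exons$sample_id, kept$exons$call_id) %in%
                             paste(k$sample_id, k$call_id), ]
          gene_length_kb(ex)
        }, numeric(1)))
      counts <- tx |>
        dplyr::group_by(.data$sample_id, .data$gene_id) |>
        dplyr::summarise(read_count = sum(.data$read_count, na.rm = TRUE),
                         .groups = "drop") |>
        tidyr::complete(.data$sample_id, .data$gene_id,
                        fill = list(read_count = 0)) |>
        dplyr::left_join(lens, by = "gene_id")
      compute_tpm(counts)
    }
  })

  # ---- target-gene transcript analysis ------------------------------------
  target_keys <- kept$transcripts[kept$transcripts$locus_label == "target",
                                  c("sample_id", "call_id")]
  target <- subset_calls(kept, target_keys)
  anno <- stage("annotate", annotate_transcripts(target, genome, orf_params))

  ref_assigned <- assign_to_locus(reference, locus)
  ref_target <- subset_calls(
    ref_assigned,
    ref_assigned$transcripts[ref_assigned$transcripts$locus_label == "target",
                             c("sample_id", "call_id")])
  ref_anno <- stage("annotate_reference",
                    annotate_transcripts(ref_target, genome, orf_params))

  orf_catalog <- stage("orf_ids",
                       assign_orf_ids(anno, locus$target_gene_id, ref_anno))
  anno$orf_id <- orf_catalog$orf_id[match(anno$orf_sig, orf_catalog$orf_sig)]
  anno$orf_id[!anno$has_orf] <- "noORF"

  anno <- stage("cluster_utrs", {
    a5 <- cluster_utrs(tibble::tibble(internal_sig = anno$utr5_sig,
                                      distal_end = anno$utr5_distal,
                                      support = anno$read_count),
                       "5", mparams)
    a3 <- cluster_utrs(tibble::tibble(internal_sig = anno$utr3_sig,
                                      distal_end = anno$utr3_distal,
                                      support = anno$read_count),
                       "3", mparams)
    anno$utr5_id <- a5$utr_id
    anno$utr3_id <- a3$utr_id
    anno
  })

  merged <- stage("merge_calls", merge_calls(anno, target))
  split <- stage("filter_valid", filter_valid(merged, cparams$min_occurrence))
  valid <- split$valid

  classified <- stage("classify",
                      classify_transcripts(valid, anno, ref_anno, cparams,
                                           mparams))

  um <- stage("usage", usage_matrix(merged))
  um_valid <- um[um$composite_id %in% valid$table$composite_id, ]
  med <- stage("median_usage", median_usage(um_valid))
  ou <- stage("orf_usage", orf_usage(um_valid, valid$table))
  ou_med <- median_usage(ou, id_col = "orf_id")
  tspec <- if (!is.null(samples)) {
    stage("tissue_specific", tissue_specific(um_valid, samples, cparams))
  } else NULL

  report <- classified |>
    dplyr::left_join(med, by = "composite_id")
  if (!is.null(tspec)) {
    report <- dplyr::left_join(report, tspec, by = "composite_id")
  }

  tss_val <- if (!is.null(tss)) stage("validate_tss",
                                      validate_tss(valid, tss, vparams)) else NULL
  pas_val <- if (!is.null(pas)) stage("validate_pas",
                                      validate_pas(valid, pas, vparams)) else NULL
  jx_val <- if (!is.null(junctions)) {
    stage("validate_junctions", validate_junctions(valid, junctions))
  } else NULL
  jx_rates <- if (!is.null(junctions) && !is.null(samples) &&
                    ncol(junctions) > 4) {
    keep_cols <- c("chrom", "intron_start", "intron_end", "strand",
                   intersect(names(junctions), samples$sample_id))
    stage("junction_rates",
          junction_detection_rates(junctions[, keep_cols], samples))
  } else NULL

  summary <- list(
    n_input_calls = n_in,
    locus_labels = as.list(label_counts),
    n_artifact_calls_removed = n_artifacts,
    n_target_calls = nrow(target_keys),
    n_merged = nrow(merged$table),
    n_valid = nrow(valid$table),
    n_discarded = nrow(split$discarded$table),
    n_novel = sum(!classified$tx_known),
    category_counts = as.list(table(classified$category)),
    n_orfs = length(unique(classified$orf_id[classified$orf_id != "noORF"])),
    n_novel_orfs = length(unique(
      classified$orf_id[classified$orf_id != "noORF" & !classified$orf_known])),
    n_utr5 = length(unique(classified$utr5_id)),
    n_utr3 = length(unique(classified$utr3_id)),
    tss_validated_fraction = if (!is.null(tss_val)) attr(tss_val, "fraction") else NA,
    pas_validated_fraction = if (!is.null(pas_val)) attr(pas_val, "fraction") else NA,
    junction_matched = if (!is.null(jx_val))
      c(matched = sum(jx_val$matched), total = nrow(jx_val)) else NULL,
    parameters = list(orf = orf_params, merge = mparams, classify = cparams,
                      validation = vparams))

  result <- structure(list(calls = calls, gene_quant = gene_quant,
                           anno = anno, orf_catalog = orf_catalog,
                           merged = merged, valid = valid,
                           discarded = split$discarded, report = report,
                           usage = um, median_usage = med,
                           orf_usage = ou, orf_median_usage = ou_med,
                           tissue_specific = tspec, tss = tss_val,
                           pas = pas_val, junctions = jx_val,
                           junction_rates = jx_rates, summary = summary),
                      class = "isocollapse_result")
  if (!is.null(out_dir)) write_result(result, out_dir)
  result
}

#' @export
print.isocollapse_result <- function(x, ...) {
  s <- x$summary
  cat("<isocollapse_result>\n",
      " input calls:        ", s$n_input_calls, "\n",
      " target calls:       ", s$n_target_calls, "\n",
      " merged transcripts: ", s$n_merged, " (valid: ", s$n_valid,
      ", sub-threshold: ", s$n_discarded, ")\n",
      " novel transcripts:  ", s$n_novel, "\n",
      " distinct ORFs:      ", s$n_orfs, " (novel: ", s$n_novel_orfs, ")\n",
      sep = "")
  invisible(x)
}

#' Write the pipeline's stage outputs as plain text files
#' @param result An `isocollapse_result`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  tsv <- function(d, f) utils::write.table(d, p(f), sep = "\t",
                                           row.names = FALSE, quote = FALSE)
  if (nrow(result$valid$table)) write_gtf(result$valid, p("valid_transcripts.gtf"))
  tsv(result$gene_quant, "gene_tpm.tsv")
  tsv(result$report, "transcript_report.tsv")
  tsv(result$merged$members, "membership.tsv")
  tsv(result$orf_catalog, "orf_catalog.tsv")
  tsv(result$usage, "usage_matrix.tsv")
  tsv(result$orf_usage, "orf_usage.tsv")
  if (!is.null(result$tss)) tsv(result$tss, "tss_validation.tsv")
  if (!is.null(result$pas)) tsv(result$pas, "pas_validation.tsv")
  if (!is.null(result$junctions)) tsv(result$junctions, "junction_validation.tsv")
  s <- result$summary
  flat <- c(n_input_calls = s$n_input_calls,
            unlist(s$locus_labels),
            n_artifact_calls_removed = s$n_artifact_calls_removed,
            n_target_calls = s$n_target_calls, n_merged = s$n_merged,
            n_valid = s$n_valid, n_discarded = s$n_discarded,
            n_novel = s$n_novel, unlist(s$category_counts),
            n_orfs = s$n_orfs, n_novel_orfs = s$n_novel_orfs,
            tss_validated_fraction = s$tss_validated_fraction,
            pas_validated_fraction = s$pas_validated_fraction)
  tsv(tibble::tibble(key = names(flat), value = unname(flat)), "summary.tsv")
  invisible(out_dir)
}
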