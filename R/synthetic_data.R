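#' Configuration for the synthetic two-gene locus simulator
#'
#' The generator emulates per-sample long-read transcript calls at a locus
#' where a target gene overlaps a readthrough gene: a minus-strand target
#' gene with nine canonical exons plus alternative-start, retained-intron,
#' exon-skipping (frameshift and in-frame), UTR-variant and non-coding
#' isoforms, a partner gene downstream, and readthrough transcripts splicing
#' the two together. Every isoform's ORF, NMD status and category are fixed
#' by construction, giving complete ground truth.
#'
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param n_samples Number of samples (default 50).
#' @param tissues Named integer vector: samples per tissue; must sum to
#'   `n_samples`.
#' @param utr_jitter_bp Maximum absolute deviation (bp) applied to each
#'   call's distal UTR ends (default 10, half the 20-bp merge tolerance so
#'   that jittered copies of one transcript always fall inside one anchored
#'   cluster). Internal boundaries and splice sites are never jittered.
#' @param jitter_override Optional named vector of per-transcript jitter
#'   overrides (bp), e.g. `c(T_combo = 40)` to force one transcript's ends
#'   beyond the merge tolerance.
#' @param dropout Per-transcript per-sample probability of non-detection
#'   (default 0.15).
#' @param count_depth Mean target-locus read depth per sample (default 5000).
#' @param usage_profile Optional matrix (11 target transcripts x tissues) of
#'   usage fractions; columns must sum to 1. Defaults to a profile in which
#'   the alternative-start isoform is 4-fold enriched in the first tissue.
#' @param tss_coverage,pas_coverage,junction_coverage Fraction of distinct
#'   truth TSSs / polyA sites / junctions included in the emitted reference
#'   sets (default 1).
#' @param target_gene,partner_gene,readthrough_gene Gene labels.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_samples = 50L,
                       tissues = c(brain = 17L, heart = 17L, blood = 16L),
                       utr_jitter_bp = 10L, jitter_override = NULL,
                       dropout = 0.15, count_depth = 5000,
                       usage_profile = NULL,
                       tss_coverage = 1, pas_coverage = 1,
                       junction_coverage = 1,
                       target_gene = "TGT", partner_gene = "NBR",
                       readthrough_gene = "RTG") {
  stopifnot(utr_jitter_bp >= 0, dropout >= 0, dropout < 1, count_depth > 0,
            sum(tissues) == n_samples, n_samples >= 1)
  cfg <- structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                        tissues = tissues, utr_jitter_bp = as.integer(utr_jitter_bp),
                        jitter_override = jitter_override, dropout = dropout,
                        count_depth = count_depth, usage_profile = usage_profile,
                        tss_coverage = tss_coverage, pas_coverage = pas_coverage,
                        junction_coverage = junction_coverage,
                        target_gene = target_gene, partner_gene = partner_gene,
                        readthrough_gene = readthrough_gene),
                   class = "sim_config")
  if (is.null(cfg$usage_profile)) {
    cfg$usage_profile <- default_usage_profile(names(tissues))
  }
  bad <- abs(colSums(cfg$usage_profile) - 1) > 1e-9
  if (any(bad)) {
    stop("usage_profile columns must sum to 1 (violated: ",
         paste(colnames(cfg$usage_profile)[bad], collapse = ", "), ")")
  }
  cfg
}

target_tx_names <- function() {
  c("T_canon", "T_ri4", "T_major", "T_nck", "T_ncn", "T_utr5", "T_3short",
    "T_combo", "T_alt", "T_ri6", "T_minor")
}

default_usage_profile <- function(tissue_names) {
  base <- c(T_canon = 0.52, T_ri4 = 0.06, T_major = 0.04, T_nck = 0.05,
            T_ncn = 0.04, T_utr5 = 0.07, T_3short = 0.06, T_combo = 0.05,
            T_alt = 0.04, T_ri6 = 0.04, T_minor = 0.03)
  enriched <- base
  enriched["T_canon"] <- 0.40
  enriched["T_alt"] <- 0.16  # 4-fold above the base tissues
  m <- matrix(rep(base, length(tissue_names)), ncol = length(tissue_names),
              dimnames = list(names(base), tissue_names))
  m[, 1] <- enriched
  m
}

# ---- locus layout (pure integer arithmetic, transcript orientation) -------

# Segment lengths along the minus strand in transcript orientation ("M"
# coordinates run 5'->3' of the genes; the plus-strand genome is the
# reverse complement).
locus_segments <- function() {
  lens <- c(flank5 = 400, E0 = 80, g0 = 300, E1ext = 70, E1 = 100,
            i1 = 4000, E2 = 150, i2 = 1750, E3ext = 50, E3 = 120,
            i3 = 3460, E4ext = 40, E4 = 90, I4 = 300, E5 = 96,
            i5 = 2000, E6 = 91, I6 = 120, E7 = 75, i7 = 3000,
            E8 = 200, E8ext = 80, I8 = 1120, E9 = 250, E9ext = 100,
            gap = 3000, PE1 = 120, ip = 900, PE2 = 150, flank3 = 400)
  m2 <- cumsum(lens)
  tibble::tibble(name = names(lens), len = unname(lens),
                 m1 = m2 - lens + 1, m2 = unname(m2))
}

truth_structures <- function() {
  list(
    T_canon = list("E1", "E2", "E3", "E4", "E5", "E6", "E7", "E8", "E9"),
    T_ri4 = list("E1", "E2", "E3", c("E4", "I4", "E5"), "E6", "E7", "E8", "E9"),
    T_major = list("E1", "E2", "E3", "E4", "E5", "E8", "E9"),
    T_nck = list(c("E4ext", "E4"), "E5", "E9"),
    T_ncn = list("E1", "E8", "E9"),
    T_utr5 = list(c("E1ext", "E1"), "E2", "E3", "E4", "E5", "E6", "E7", "E8", "E9"),
    T_3short = list("E1", "E2", "E3", "E4", "E5", "E6", "E7", c("E8", "E8ext")),
    T_combo = list("E0", "E2", "E3", "E4", "E5", "E6", "E7", "E8", "E9"),
    T_alt = list(c("E3ext", "E3"), "E4", "E5", "E6", "E7", "E8", "E9"),
    T_ri6 = list("E1", "E2", "E3", "E4", "E5", c("E6", "I6", "E7"), "E8", "E9"),
    T_minor = list("E1", "E2", "E3", "E6", "E7", "E8", "E9"),
    T_rt = list("E1", "E2", "E3", "PE1", "PE2"),
    T_p = list("PE1", "PE2"))
}

ref_only_structures <- function() {
  list(R2 = list("E0", "E2", "E3", "E4", "E5", "E6", "E7", "E8",
                 c("E9", "E9ext")))
}

seg_pos <- function(segs, name, offset) {
  segs$m1[segs$name == name] + offset - 1L
}

# M intervals (one per exon) for a structure definition; merged blocks must
# be contiguous segments.
structure_intervals <- function(segs, def) {
  out <- lapply(def, function(parts) {
    rows <- segs[match(parts, segs$name), ]
    stopifnot(!anyNA(rows$m1))
    if (nrow(rows) > 1) {
      stopifnot(all(rows$m1[-1] == rows$m2[-nrow(rows)] + 1L))
    }
    c(min(rows$m1), max(rows$m2))
  })
  tibble::tibble(m1 = vapply(out, `[`, numeric(1), 1),
                 m2 = vapply(out, `[`, numeric(1), 2))
}

spliced_m_positions <- function(segs, def) {
  iv <- structure_intervals(segs, def)
  unlist(lapply(seq_len(nrow(iv)), function(i) seq.int(iv$m1[i], iv$m2[i])))
}

codon_triples <- function(positions) {
  stopifnot(length(positions) %% 3 == 0)
  matrix(positions, ncol = 3, byrow = TRUE)
}

# Planted codons and frame constraints that realize the designed ORFs.
locus_constraints <- function(segs) {
  at <- function(name, offset) seg_pos(segs, name, offset) + 0:2
  forced <- list(
    list(pos = at("E2", 31), codon = "ATG", is_start = TRUE),
    list(pos = at("E4", 1), codon = "ATG", is_start = TRUE),
    list(pos = at("E8", 168), codon = "TAA"),
    list(pos = at("I4", 241), codon = "TAA"),
    list(pos = at("E8", 100), codon = "TAA"),
    list(pos = at("E9", 31), codon = "TAA"),
    list(pos = at("PE1", 31), codon = "TAA"))

  # canonical CDS frame: E2[31..150] .. E8[1..170], stop codon excluded
  canon_cds <- c(seq.int(seg_pos(segs, "E2", 31), seg_pos(segs, "E2", 150)),
                 spliced_m_positions(segs, list("E3", "E4", "E5", "E6", "E7")),
                 seq.int(seg_pos(segs, "E8", 1), seg_pos(segs, "E8", 170)))
  canon <- codon_triples(canon_cds)
  canon <- canon[-nrow(canon), , drop = FALSE]

  tri <- function(name, from, to) {
    codon_triples(seq.int(seg_pos(segs, name, from), seg_pos(segs, name, to)))
  }
  not_stop <- rbind(
    canon,
    tri("I4", 1, 240),                                  # retained-intron frame
    tri("E8", 1, 99),                                   # frameshift (exon-skip) frame
    matrix(c(seg_pos(segs, "E6", 91), seg_pos(segs, "I6", 1),
             seg_pos(segs, "I6", 2)), ncol = 3),        # I6 entry codon
    tri("I6", 3, 119),
    matrix(c(seg_pos(segs, "I6", 120), seg_pos(segs, "E7", 1),
             seg_pos(segs, "E7", 2)), ncol = 3),        # I6 exit codon
    tri("E9", 1, 30),                                   # short downstream ORF frame
    tri("PE1", 1, 30))                                  # readthrough ORF frame

  # spliced junction windows must not create ATG across any truth junction
  defs <- c(truth_structures(), ref_only_structures())
  not_atg <- list()
  for (def in defs) {
    iv <- structure_intervals(segs, def)
    if (nrow(iv) < 2) next
    for (i in seq_len(nrow(iv) - 1)) {
      a2 <- iv$m2[i]; b1 <- iv$m1[i + 1]
      not_atg <- c(not_atg, list(c(a2 - 1, a2, b1), c(a2, b1, b1 + 1)))
    }
  }
  not_atg <- unique(not_atg)
  list(forced = forced, not_stop = not_stop,
       not_atg = do.call(rbind, not_atg))
}

# Generate the transcript-orientation locus sequence by left-to-right
# rejection sampling under the planted/forbidden codon constraints, then
# verify every constraint.
generate_locus_seq <- function(segs, constraints) {
  L <- max(segs$m2)
  stops <- c("TAA", "TAG", "TGA")
  forced_base <- rep(NA_character_, L)
  atg_starts <- integer(0)
  for (f in constraints$forced) {
    forced_base[f$pos] <- strsplit(f$codon, "")[[1]]
    if (isTRUE(f$is_start)) atg_starts <- c(atg_starts, f$pos[1])
  }
  tri_all <- rbind(constraints$not_stop, constraints$not_atg)
  tri_type <- c(rep("stop", nrow(constraints$not_stop)),
                rep("atg", nrow(constraints$not_atg)))
  tri_max <- pmax(tri_all[, 1], tri_all[, 2], tri_all[, 3])
  by_max <- split(seq_len(nrow(tri_all)), tri_max)
  M <- character(L)
  bases <- c("A", "C", "G", "T")
  for (p in seq_len(L)) {
    if (!is.na(forced_base[p])) {
      M[p] <- forced_base[p]
      next
    }
    checks <- by_max[[as.character(p)]]
    cand <- sample(bases)
    placed <- FALSE
    for (b in cand) {
      ok <- TRUE
      if (p >= 3 && !(p - 2) %in% atg_starts &&
          M[p - 2] == "A" && M[p - 1] == "T" && b == "G") ok <- FALSE
      if (ok && !is.null(checks)) {
        M[p] <- b  # tentatively, so triple lookup sees it
        for (ci in checks) {
          w <- paste0(M[tri_all[ci, 1]], M[tri_all[ci, 2]], M[tri_all[ci, 3]])
          if ((tri_type[ci] == "stop" && w %in% stops) ||
              (tri_type[ci] == "atg" && w == "ATG")) { ok <- FALSE; break }
        }
      }
      if (ok) { M[p] <- b; placed <- TRUE; break }
    }
    if (!placed) stop("unsatisfiable sequence constraint at position ", p)
  }
  seq <- paste(M, collapse = "")
  # verification pass: planted codons, frames, and global ATG occurrences
  for (f in constraints$forced) {
    stopifnot(substr(seq, f$pos[1], f$pos[3]) == f$codon)
  }
  for (i in seq_len(nrow(tri_all))) {
    w <- paste0(M[tri_all[i, 1]], M[tri_all[i, 2]], M[tri_all[i, 3]])
    bad <- (tri_type[i] == "stop" && w %in% stops) ||
      (tri_type[i] == "atg" && w == "ATG")
    if (bad) stop("constraint violated after generation (triple ", i, ")")
  }
  hits <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  hits <- hits[hits > 0]
  if (!setequal(hits, atg_starts)) {
    stop("unplanned ATG in generated locus sequence")
  }
  seq
}

m_to_genomic <- function(L, m1, m2) {
  tibble::tibble(start = L - m2 + 1, end = L - m1 + 1)
}

structure_exons <- function(segs, def, L, chrom, sample_id, call_id) {
  iv <- structure_intervals(segs, def)
  g <- m_to_genomic(L, iv$m1, iv$m2)
  tibble::tibble(sample_id = sample_id, call_id = call_id,
                 exon_rank = seq_len(nrow(iv)), chrom = chrom,
                 start = g$start, end = g$end, strand = "-")
}

# ---- ground truth ---------------------------------------------------------

truth_meta_table <- function() {
  tibble::tribble(
    ~name,      ~locus,       ~in_ref, ~orf_label, ~protein_length, ~nmd,  ~category,
    "T_canon",  "target",      TRUE,  "O_canon",  253L, FALSE, "Coding_Known",
    "T_ri4",    "target",      TRUE,  "O_ri4",    190L, TRUE,  "NMD_Known",
    "T_major",  "target",      FALSE, "O_major",  175L, TRUE,  "NMD_Novel",
    "T_nck",    "target",      TRUE,  "O_small",  72L,  FALSE, "Non_coding_Known",
    "T_ncn",    "target",      FALSE, NA,         NA,   FALSE, "Non_coding_Novel",
    "T_utr5",   "target",      FALSE, "O_canon",  253L, FALSE, "Novel_3/5UTR_only",
    "T_3short", "target",      FALSE, "O_canon",  253L, FALSE, "Novel_3/5UTR_only",
    "T_combo",  "target",      FALSE, "O_canon",  253L, FALSE, "Novel_combination",
    "T_alt",    "target",      FALSE, "O_alt",    173L, FALSE, "Novel_ORF_and_UTR",
    "T_ri6",    "target",      FALSE, "O_ri6",    293L, FALSE, "Novel_ORF_only",
    "T_minor",  "target",      FALSE, "O_minor",  191L, FALSE, "Novel_ORF_only",
    "T_rt",     "readthrough", FALSE, "O_rt",     90L,  TRUE,  NA,
    "T_p",      "partner",     FALSE, NA,         NA,   NA,    NA)
}

#' Build the synthetic locus, its ground truth and the reference sets
#'
#' Deterministic given `cfg$seed`. Returns the toy genome, the truth
#' transcript catalog (with each isoform's designed ORF length, NMD flag
#' and category), the reference annotation subset marked known, and
#' TSS/polyA/junction reference sets covering the configured fraction of
#' truth ends.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_truth` list: `genome` (DNAStringSet), `chrom`, `truth`
#'   (a [transcript_set()] of the 13 truth models, sample `"truth"`),
#'   `meta` (per-transcript ground truth), `reference` (a `transcript_set`
#'   of the annotation models), `locus` (a [locus_config()]), `tss`, `pas`,
#'   `junctions` (reference interval tibbles), `usage_profile`.
#' @export
build_truth <- function(cfg = sim_config()) {
  withr::with_seed(cfg$seed, build_truth_impl(cfg))
}

build_truth_impl <- function(cfg) {
  segs <- locus_segments()
  L <- max(segs$m2)
  chrom <- "chrS"
  mseq <- generate_locus_seq(segs, locus_constraints(segs))
  genome <- Biostrings::DNAStringSet(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(mseq))))
  names(genome) <- chrom

  defs <- truth_structures()
  meta <- truth_meta_table()
  exons <- dplyr::bind_rows(lapply(names(defs), function(nm) {
    structure_exons(segs, defs[[nm]], L, chrom, "truth", nm)
  }))
  gene_of <- c(target = cfg$target_gene, readthrough = cfg$readthrough_gene,
               partner = cfg$partner_gene)
  truth_tx <- tibble::tibble(
    sample_id = "truth", call_id = meta$name,
    gene_label = unname(gene_of[meta$locus]),
    caller_status = ifelse(meta$in_ref, "Known", "Novel"),
    gene_status = "Known", read_count = NA_real_)
  truth <- transcript_set(truth_tx, exons)

  ref_defs <- c(defs[meta$name[meta$in_ref]], ref_only_structures(),
                list(R_p = truth_structures()$T_p))
  ref_exons <- dplyr::bind_rows(lapply(names(ref_defs), function(nm) {
    structure_exons(segs, ref_defs[[nm]], L, chrom, "reference", nm)
  }))
  ref_tx <- tibble::tibble(
    sample_id = "reference", call_id = names(ref_defs),
    gene_label = ifelse(names(ref_defs) == "R_p", cfg$partner_gene,
                        cfg$target_gene),
    caller_status = "other", gene_status = "other", read_count = NA_real_)
  reference <- transcript_set(ref_tx, ref_exons)

  span_of <- function(from, to, margin = 60) {
    g <- m_to_genomic(L, segs$m1[segs$name == from] - margin,
                      segs$m2[segs$name == to] + margin)
    sprintf("%s:%d-%d:-", chrom, g$start, g$end)
  }
  locus <- locus_config(target_locus = span_of("E0", "E9ext"),
                        partner_locus = span_of("PE1", "PE2"),
                        target_gene_id = cfg$target_gene,
                        partner_gene_id = cfg$partner_gene,
                        readthrough_gene_id = cfg$readthrough_gene)

  # reference end sets: distinct truth termini, covered fraction, +-10 bp peaks
  end_set <- function(side, coverage) {
    pts <- vapply(meta$name, function(nm) {
      tx_terminus(exon_chain(truth, "truth", nm), side)
    }, numeric(1))
    u <- sort(unique(pts))
    k <- round(coverage * length(u))
    covered <- u[seq_len(k)]
    tibble::tibble(chrom = chrom, start = covered - 10, end = covered + 10,
                   strand = "-",
                   kind = if (side == "5") "tss" else "pas")
  }
  tss <- end_set("5", cfg$tss_coverage)
  pas <- end_set("3", cfg$pas_coverage)

  all_introns <- dplyr::distinct(dplyr::bind_rows(lapply(meta$name, function(nm) {
    tx_introns(exon_chain(truth, "truth", nm))
  })))
  all_introns <- all_introns[order(all_introns$start, all_introns$end), ]
  kj <- round(cfg$junction_coverage * nrow(all_introns))
  junctions <- tibble::tibble(chrom = all_introns$chrom[seq_len(kj)],
                              intron_start = all_introns$start[seq_len(kj)],
                              intron_end = all_introns$end[seq_len(kj)],
                              strand = all_introns$strand[seq_len(kj)])

  structure(list(genome = genome, chrom = chrom, segments = segs,
                 truth = truth, meta = meta, reference = reference,
                 locus = locus, tss = tss, pas = pas,
                 junctions = junctions, all_introns = all_introns,
                 usage_profile = cfg$usage_profile, cfg = cfg),
            class = "sim_truth")
}

# shift a distal end of an exon chain by delta (positive = extend outward)
adjust_distal <- function(ex, side, delta) {
  if (delta == 0) return(ex)
  minus <- ex$strand[1] == "-"
  n <- nrow(ex)
  if (side == "5") {
    if (minus) ex$end[1] <- ex$end[1] + delta else ex$start[1] <- ex$start[1] - delta
  } else {
    if (minus) ex$start[n] <- ex$start[n] - delta else ex$end[n] <- ex$end[n] + delta
  }
  stopifnot(all(ex$end >= ex$start))
  ex
}

#' Simulate per-sample transcript calls, read counts and junction counts
#'
#' Each truth transcript is detected per sample with probability
#' `1 - dropout`; detected calls have their distal UTR ends jittered
#' uniformly within `+-utr_jitter_bp` (splice sites untouched); target-locus
#' read counts are multinomial at the drawn sample depth with the
#' tissue-specific usage profile; readthrough and partner transcripts get
#' independent Poisson counts; one decoy call per sample carries the caller
#' label `"Genomic"`. Junction counts are the summed read counts of the
#' sample's calls containing each junction.
#'
#' @param truth A `sim_truth` from [build_truth()].
#' @param cfg The same [sim_config()].
#' @return A `sim_samples` list: `calls` (a [transcript_set()] over all
#'   samples, read counts filled), `quant` (long count table), `samples`
#'   (sample-to-tissue map), `junction_counts` (wide per-sample table),
#'   `detection` (logical truth-by-sample matrix).
#' @export
simulate_samples <- function(truth, cfg = truth$cfg) {
  withr::with_seed(cfg$seed + 1L, simulate_samples_impl(truth, cfg))
}

simulate_samples_impl <- function(truth, cfg) {
  meta <- truth$meta
  tnames <- meta$name
  target <- meta$name[meta$locus == "target"]
  sample_ids <- sprintf("s%02d", seq_len(cfg$n_samples))
  tissue_of <- rep(names(cfg$tissues), cfg$tissues)
  profile <- cfg$usage_profile[target, , drop = FALSE]

  detection <- matrix(FALSE, length(tnames), cfg$n_samples,
                      dimnames = list(tnames, sample_ids))
  all_tx <- list(); all_ex <- list(); quant <- list()
  jx <- truth$all_introns
  jx_counts <- matrix(0, nrow(jx), cfg$n_samples,
                      dimnames = list(NULL, sample_ids))
  jitter_of <- function(nm) {
    j <- cfg$utr_jitter_bp
    if (!is.null(cfg$jitter_override) && nm %in% names(cfg$jitter_override)) {
      j <- cfg$jitter_override[[nm]]
    }
    j
  }
  for (si in seq_along(sample_ids)) {
    s <- sample_ids[si]
    det <- stats::runif(length(tnames)) >= cfg$dropout
    if (!any(det)) det <- stats::runif(length(tnames)) >= cfg$dropout
    if (!any(det)) warning("no transcript detected in sample ", s)
    detection[, si] <- det
    names(det) <- tnames
    depth <- stats::rpois(1, cfg$count_depth)
    counts <- stats::setNames(numeric(length(tnames)), tnames)
    dt <- target[det[target]]
    if (length(dt) && depth > 0) {
      counts[dt] <- as.vector(stats::rmultinom(1, depth,
                                               profile[dt, tissue_of[si]]))
    }
    for (nm in c("T_rt", "T_p")) {
      if (det[nm]) counts[nm] <- stats::rpois(1, 0.05 * cfg$count_depth)
    }
    for (nm in tnames[det]) {
      ex <- exon_chain(truth$truth, "truth", nm)
      j <- jitter_of(nm)
      if (j > 0) {
        ex <- adjust_distal(ex, "5", sample.int(2 * j + 1, 1) - j - 1)
        ex <- adjust_distal(ex, "3", sample.int(2 * j + 1, 1) - j - 1)
      }
      cid <- paste0(nm, ".", s)
      ex$sample_id <- s; ex$call_id <- cid
      all_ex[[length(all_ex) + 1]] <- ex
      all_tx[[length(all_tx) + 1]] <- tibble::tibble(
        sample_id = s, call_id = cid,
        gene_label = truth$truth$transcripts$gene_label[
          truth$truth$transcripts$call_id == nm],
        caller_status = ifelse(meta$in_ref[meta$name == nm], "Known", "Novel"),
        gene_status = "Known", read_count = counts[nm])
      quant[[length(quant) + 1]] <- tibble::tibble(
        sample_id = s, call_id = cid, read_count = counts[nm])
      introns <- tx_introns(exon_chain(truth$truth, "truth", nm))
      if (nrow(introns)) {
        hit <- paste(jx$start, jx$end) %in% paste(introns$start, introns$end)
        jx_counts[hit, si] <- jx_counts[hit, si] + counts[nm]
      }
    }
    # decoy artifact call: canonical structure labeled "Genomic"
    dex <- exon_chain(truth$truth, "truth", "T_canon")
    dcid <- paste0("decoy.", s)
    dex$sample_id <- s; dex$call_id <- dcid
    all_ex[[length(all_ex) + 1]] <- dex
    all_tx[[length(all_tx) + 1]] <- tibble::tibble(
      sample_id = s, call_id = dcid, gene_label = cfg$target_gene,
      caller_status = "Genomic", gene_status = "Known",
      read_count = 5 + stats::rpois(1, 5))
    quant[[length(quant) + 1]] <- tibble::tibble(
      sample_id = s, call_id = dcid,
      read_count = all_tx[[length(all_tx)]]$read_count)
  }
  calls <- transcript_set(dplyr::bind_rows(all_tx), dplyr::bind_rows(all_ex))
  junction_counts <- dplyr::bind_cols(
    tibble::tibble(chrom = jx$chrom, intron_start = jx$start,
                   intron_end = jx$end, strand = jx$strand),
    tibble::as_tibble(jx_counts))
  structure(list(calls = calls, quant = dplyr::bind_rows(quant),
                 samples = tibble::tibble(sample_id = sample_ids,
                                          tissue = tissue_of),
                 junction_counts = junction_counts,
                 detection = detection),
            class = "sim_samples")
}

#' Write a simulation to disk in the pipeline's input formats
#'
#' Emits `genome.fa`, `ref.gtf`, `tss.bed`, `pas.bed`, `junctions_ref.tsv`,
#' `junction_counts.tsv`, `samples.tsv`, truth tables, and one GTF + one
#' quantification TSV per sample under `dir`.
#'
#' @param truth A `sim_truth`.
#' @param sim A `sim_samples`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths (with `gtf` and
#'   `quant` vectors for the per-sample files).
#' @export
write_simulation <- function(truth, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(truth$genome, p("genome.fa"))
  write_gtf(truth$reference, p("ref.gtf"))
  write_bed_intervals(truth$tss, p("tss.bed"))
  write_bed_intervals(truth$pas, p("pas.bed"))
  utils::write.table(truth$junctions, p("junctions_ref.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(sim$junction_counts, p("junction_counts.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(sim$samples, p("samples.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(truth$meta, p("truth_transcripts.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  up <- tibble::as_tibble(truth$usage_profile, rownames = "name")
  utils::write.table(up, p("truth_usage.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  gtfs <- character(0); quants <- character(0)
  for (s in sim$samples$sample_id) {
    ss <- subset_calls(sim$calls,
                       sim$calls$transcripts[sim$calls$transcripts$sample_id == s,
                                             c("sample_id", "call_id")])
    gtfs[s] <- p(paste0(s, ".gtf"))
    write_gtf(ss, gtfs[s])
    q <- sim$quant[sim$quant$sample_id == s, ]
    quants[s] <- p(paste0(s, "_quant.tsv"))
    utils::write.table(
      tibble::tibble(sample_id = q$sample_id, transcript_id = q$call_id,
                     read_count = q$read_count),
      quants[s], sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(list(genome = p("genome.fa"), ref_gtf = p("ref.gtf"),
                 tss = p("tss.bed"), pas = p("pas.bed"),
                 junctions_ref = p("junctions_ref.tsv"),
                 junction_counts = p("junction_counts.tsv"),
                 samples = p("samples.tsv"), gtf = gtfs, quant = quants))
}
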