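---
title: "Methods: locus-centric isoform collapse, classification and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus-centric isoform collapse, classification and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocollapse)
```

## The problem

Long-read RNA-seq callers emit transcript models per sample, with
sample-specific identifiers and small variability at transcript ends. For a
gene of interest this leaves three obstacles between the raw calls and a
usable isoform catalog: (i) at loci with an annotated readthrough
(conjoined) gene, calls must first be attributed to the right gene, because
the readthrough duplicates exon sequence and absorbs expression that naive
per-gene counting would misassign; (ii) equivalent isoforms must be
recognised across samples despite end variability; (iii) the merged
transcripts need interpretable identities and functional annotations (ORF,
NMD liability, novelty) before usage statistics mean anything.

`isocollapse` implements this as a deterministic pipeline over plain
containers (a `transcript_set` is a transcript table plus an exon table,
1-based inclusive coordinates, exon chains ordered 5′→3′ in transcript
orientation). All interval arithmetic is delegated to
IRanges/GenomicRanges, sequence work to Biostrings, and GTF/BED parsing to
rtracklayer; the scientific operations — the merge criteria, the ORF and
NMD rules, the category cascade — are implemented and tested here.

## Procedure and assumptions

**Locus assignment** compares each call's genomic span (first to last
exon) with the two configured loci, strand-aware, ≥ 1 bp overlap. Span
overlap (rather than exonic overlap) matches range-based selection of
transcripts at a locus; an `exonic_only` switch is provided. Calls
overlapping neither locus, or only the partner locus, are excluded from
both genes but counted in the pipeline log.

**Gene length for TPM** is the union of exonic bases over the transcripts
assigned to the gene in the dataset at hand, not the annotated span. This
is the standard reads-per-kilobase denominator when the observed transcript
structures are the quantification targets; it is recorded in the output so
TPMs are interpretable. All retained genes at the locus pair enter the
per-sample TPM denominator.

**ORF prediction** scans the three forward frames of the spliced sequence:
`ATG` start, `TAA|TAG|TGA` stops, codons containing `N` match neither. For
each distinct stop codon only the longest ORF is kept (the most upstream
compatible start); the transcript's ORF is then the longest candidate, ties
resolved toward the most 5′ start. ORFs without an in-frame stop before the
transcript end are discarded — ORFs are keyed on stop codons, and an
unterminated reading frame has no defined product. Products are translated
without the stop, so a 762-nt CDS yields a 253-aa protein.

**ORF identity and IDs.** Two ORFs are the same iff their genomic CDS
block sets are identical; the same peptide reached through different
genomic paths is deliberately kept distinct, because IDs attach to
transcript structures. IDs are `GENE_{rank}_{length}aa`, ranked by
descending product length over the union of detected and reference ORFs
(so canonical reference isoforms keep stable ranks even when sub-threshold
detections shrink the valid set), with ties broken by 5′-most genomic CDS
start and then lexicographic block signature — fully deterministic under
input permutation.

**UTR decomposition and merging.** Each transcript's 5′/3′ UTR record
keeps its genomic blocks, its *internal boundaries* (every block edge
except the distal terminus) and the distal terminus itself. Calls merge
when they share the ORF, both internal-boundary sets, and distal ends
within the 20-bp tolerance (inclusive: a 20-bp difference merges, 21 bp
does not). Clustering is *anchored*, not single-linkage: records are
ordered by read support then coordinate, each record joins the first
anchor within tolerance or founds a new cluster. Anchoring bounds every
cluster's diameter — 20-bp steps cannot chain 0→20→40 into one cluster —
and makes the partition independent of input order. Transcripts with no
ORF are merged on full exon-structure identity with the same end
tolerance, under the ORF label `noORF`, so non-coding isoforms still get
stable IDs. UTR cluster numbers are arbitrary but reproducible for a given
input; the cluster tables are part of the output so IDs can be mapped
across runs. Empty UTRs (CDS reaching the transcript end) form a single
`5UTR_0`/`3UTR_0` class.

**NMD** follows the 50-nt rule, measured in spliced coordinates from the
last base of the stop codon to the most downstream exon–exon junction,
strictly greater than 50; single-exon transcripts are exempt.

**Novelty and categories.** The reference annotation is pushed through the
identical ORF/UTR engine, and novelty is structural: an ORF is known iff
its CDS blocks equal a reference ORF's; a UTR is known iff a reference UTR
matches boundaries exactly and its distal end within the merge tolerance;
a transcript is known iff one reference transcript matches it under all
three merge criteria. Caller-provided `Known` labels are carried through as
corroborating metadata but do not decide novelty — novelty must mean
"absent from the reference", and structural comparison is the only
direction of that test that is internally consistent. The category cascade
is total and ordered: NMD first (split known/novel), then non-coding
(no ORF or product < 150 aa), then `Coding_Known`, then the novel coding
split by ORF/UTR novelty (`Novel_3/5UTR_only`, `Novel_combination`,
`Novel_ORF_and_UTR`, `Novel_ORF_only`).

**Usage.** Usage is a within-locus read-count fraction per sample; median
usage is taken over the samples where the transcript is detected with
non-zero usage — a transcript seen in 22 of 99 samples is summarised over
those 22, which is the convention that keeps sparsely detected isoforms
comparable (an all-samples variant is a one-line change on the usage
table). Tissue summaries are per-tissue means of usage; the 2× rule is
inclusive, and a transcript expressed in exactly one tissue is specific to
it (its competitors' means are zero).

**Validation.** End validation measures the distance from a transcript
terminus to the nearest compatible interval *edge* (0 inside), because TSS
peaks and polyA clusters are intervals, not points; a strand of `.`/`*` on
a reference record matches either strand. The TSS tolerance is 50 bp; the
PAS tolerance has no canonical value, so the same 50 bp is the default and
is configurable and reported. Junction matching is exact on intron
coordinates and strand. Tryptic peptides use cleavage after K/R except
before P, zero missed cleavages, minimum length 6 (seven-residue
junction-spanning peptides are the shortest informative case in this
setting) — peptide search engines and FDR control are out of scope.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `end_tolerance` | 20 | bp | distal-end window for UTR clustering and merging |
| `nmd_distance` | 50 | nt | stop-to-last-junction threshold (strict >) |
| `coding_min_aa` | 150 | aa | products below this are non-coding |
| `tissue_fold` | 2 | × | inclusive tissue-specificity fold |
| `min_occurrence` | 3 | samples | validity threshold |
| `tss_tolerance`, `pas_tolerance` | 50 | bp | end-validation windows |

## What the synthetic locus emulates — and what it does not

`build_truth()` lays out a ~22.6-kb toy chromosome holding a minus-strand
nine-exon target gene (~18 kb), a partner gene downstream, and transcripts
that splice the two together, mirroring the target/readthrough
arrangement. The eleven target isoforms realise every category archetype:
the canonical coding transcript; a reference-annotated retained-intron
isoform whose ORF terminates inside the intron far upstream of downstream
junctions (NMD, known); a frameshift double-exon-skip whose premature stop
sits 98 nt upstream of the last junction (NMD, novel — the analogue of a
disease-associated Δ-exon transcript); an in-frame exon-skip; a coding-
region retained intron that extends the product in frame; an
alternative-start isoform with a shorter product; a 72-aa short-ORF
isoform; a no-ORF isoform; 5′-extended, alternative-first-exon and
short-3′UTR variants. The genome sequence is generated by left-to-right
rejection sampling under explicit codon constraints — planted start/stop
codons, stop-free frames where ORFs must run through, and no `ATG`
anywhere else (including across splice junctions) — so every ORF, NMD
flag and category is fixed by construction and verified after generation;
designed truth quantities are re-derived, not assumed, when the pipeline
is scored against them.

`simulate_samples()` emulates per-sample calling: Bernoulli detection
(default dropout 0.15), uniform distal-end jitter, multinomial read counts
at Poisson-drawn depth (default mean 5000) under per-tissue usage
profiles (the alternative-start isoform is 4× enriched in the first
tissue, so the 2× rule's expected flags are known analytically), Poisson
counts for the readthrough and partner transcripts, and one `Genomic`
decoy call per sample. Default scale is 50 samples across three tissues —
a deliberately desk-scale stand-in for a ~100-sample multi-organ cohort.

The generator's jitter is `utr_jitter_bp = 10` by default: the maximum
per-end deviation from the truth terminus. Under anchored clustering the
guarantee "jittered copies of one transcript form one cluster" requires
the *pairwise* spread (at most twice the per-end deviation) to stay within
the 20-bp tolerance; ±10 bp is therefore the largest jitter under which
exact catalog recovery is provable, and the controlled-violation arm
(`jitter_override = c(T_combo = 40)`) demonstrates the converse — the
forced transcript fragments while all others stay intact.

What the simulation does **not** model: splice-site noise (upstream
callers are assumed to have corrected splice sites, as TALON-style
pipelines do), read-level error profiles, internal-priming or degradation
artifacts beyond the `Genomic` decoy, partially overlapping gene
families, and real tissue covariance of isoform usage. Passing tests
therefore certify the algorithmic contracts — disambiguation, merging,
classification, statistics — on well-formed calls, not robustness to
caller pathologies.

## Numerical and design choices

- Usage-recovery checks run with dropout 0: with detection dropout the
  within-sample renormalisation inflates every detected transcript's
  usage by a factor ≈ 1/(1 − d·(1 − u)), so "recovering the designed
  profile" is only defined without dropout. Dropout is exercised where it
  belongs: occurrence, validity filtering and merge recovery.
- TPM is undefined for a sample with zero total RPK; the pipeline errors
  on such samples rather than emitting zeros.
- Median usage, anchors and ORF ranks all carry explicit deterministic
  tie-breaks (documented above), so reruns are bit-identical.
- The reference's UTRs enter novelty comparison with the same 20-bp
  tolerance used for merging — a looser or tighter novelty window would
  make "known" and "merged-with-a-known" disagree.
- Test problem sizes: exhaustive ORF-oracle comparison over all sequences
  of length ≤ 6 plus 1000 random 300-nt sequences; merge/usage recovery at
  50 samples; generator invariants across multiple seeds with jitter up to
  the tolerance. These sizes make every property check exact or
  high-powered while keeping the suite fast.

## Known limitations

- Only AUG-initiated ORFs; no Kozak scoring, non-AUG starts or
  selenocysteine recoding.
- Novelty is defined against a single reference annotation; cross-catalog
  novelty (multiple annotation versions) is out of scope.
- The readthrough model handles one partner locus; chains of more than two
  conjoined genes are not modelled.
- Validation is overlap-based corroboration, not probabilistic evidence
  integration; junction atlases with fuzzy coordinates should be
  pre-normalised to intron coordinates.
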