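---
title: "Methods: tracing duplicate-gene fate in an allohexaploid transcriptome"
author: "polyfate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracing duplicate-gene fate in an allohexaploid transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Allohexaploid bread wheat carries three diverged subgenomes (A, B and D),
so almost every gene exists as a homoeologous triplet; on top of that the
grass lineage shares an ancient whole-genome duplication whose paralog
pairs are still detectable as collinear blocks, and tandem duplication
keeps adding copy-number variants (CNVs). After any duplication the
redundant copies erode: copies are deleted or pseudogenised (structural
loss) or drift apart in where and when they are expressed (sub- or
neofunctionalisation). `polyfate` implements the full chain of analyses
needed to quantify that erosion from expressed-sequence reads of a grain
transcriptome: read clustering into unigenes, homology scoring against a
diploid reference genome, classification of ortholog / tandem-CNV /
presence-absence relationships, homoeolog copy counting, synteny-based
virtual gene ordering, duplicate-fate statistics, and a temporal model of
how the shuffled fraction grows with time since duplication.

Because the real sequencing data and genome annotations are large and
external, the package is exercised end-to-end on a synthetic allohexaploid
transcriptome generator whose planted truth lets every stage be scored
exactly.

## The synthetic transcriptome generator

`sim_config()` fixes the study conditions. The defaults encode the
biology the analysis assumes:

* **three subgenomes** diverged so that sibling copies differ at a
  configurable pairwise homoeo-SNP density, default 1/500 bases. Each
  copy is mutated from the ancestral sequence at *half* that rate, so
  the *pairwise* sibling density matches the configured value. The
  substitution model is uniform random base change: no indels, no
  transition bias, no sequencing-error model — a density is assumed, not
  a mutation process.
* **homoeolog loss**: each A/B/D copy is deleted independently with
  `homoeolog_loss_prob` (default 0.2), so triplet retention follows the
  closed form $(1-q)^3$ and, among detectable genes,
  $(1-q)^3 / (1-q^3)$.
* **expression truth** over five grain developmental stages: each gene
  has an ancestral stage-presence profile (each stage present with
  probability 0.8, at least one present); a copy diverges with
  `expr_divergence_prob` (default 0.3), in which case each stage flag
  flips with probability `expr_divergence_prob / n_stages` and one
  random flip is forced if none occurred. The two-stage draw makes the
  marginal per-copy divergence rate equal the parameter exactly, which
  is what the parameter-recovery tests check.
* **ancestral duplication blocks**: a configurable fraction of genes
  (default 0.2) lies in collinear blocks whose partner copies sit on a
  different chromosome at 8 % sequence divergence; each block member
  may be anciently lost (`paralog_loss_prob`, default 0.4), deleting its
  whole homoeolog triplet.
* **tandem CNVs**: with `cnv_prob` a gene gains an immediately adjacent
  copy that inherits the parent sequence with fresh SNPs at the
  homoeolog rate — so CNVs are distinguishable from homoeologs only by
  genomic position, which is exactly the evidence the classifier is
  allowed to use.
* **reads**: per expressed copy, read counts are Poisson with expected
  depth 25; read lengths are uniform on 400–900 bases, strands random,
  identifiers opaque. Deleted or silent copies never emit reads.

Identical seed and configuration give bit-identical outputs, including
the on-disk FASTA/GFF3/TSV files (coordinates are 0-based half-open
internally and converted to 1-based closed GFF3 on write).

What the generator does *not* emulate: 454 homopolymer errors, indels,
quality values, expression-level noise within a stage, intron structure,
or a separately dated D-genome divergence (all three subgenomes share
one SNP rate; the much younger D hybridisation is not modelled
separately). Passing tests therefore show the analysis logic is correct
under idealised reads; they do not certify robustness to real 454 error
profiles.

## Read clustering

`cluster_reads()` performs greedy transitive (single-linkage)
clustering: reads join a cluster iff connected by a chain of pairwise
overlaps of at least 40 bases at 90 % identity or better (both
parameters exposed). Candidate pairs are proposed by shared exact
16-base seeds in either orientation; each candidate is verified by
ungapped extension around the seed, which is exact for the
substitution-only read model (a banded or gapped verifier would be
needed for indel-bearing reads). The proprietary assembler scoring
scheme of the original 454 software is not reconstructed; only the
seed/overlap/identity rules are honoured. Reads are processed in a
canonical order (decreasing length, then sequence), making the result
invariant to input order up to relabelling. The consensus is the
per-column majority base over the pileup, ties broken by the
first-placed base; coverage is total member bases over consensus length.

A consequence worth understanding: with error-free reads, *any* sibling
read pair whose overlap happens to contain no homoeo-SNP is identical
there, and single linkage then merges the whole copies. At 1 SNP/500 b
the probability that a 40-base overlap is SNP-free is high, so
homoeologous copies co-assemble frequently — the merged-homoeolog
phenomenon. This is quantified, not fought: `flag_merged_homoeologs()`
flags clusters whose read count exceeds `k = 3.5` times the single-copy
centre of the read-count distribution (the multiplier reproduces a
140-read flag against a ~40-read single-copy mean). The centre is
estimated by the median rather than the mean, because the inflated tail
being flagged would otherwise contaminate its own threshold.

## Homology: AL, CIP, CALP and relationship calls

For every query–subject pair the local-alignment HSPs are chained:
overlapping query intervals are merged, with overlapped regions credited
to the higher-bitscore HSP and identities prorated by the span
retained. With AL the total merged span,

$$\mathrm{CIP} = 100 \cdot \frac{\sum \text{identities}}{\mathrm{AL}},
\qquad \mathrm{CALP} = \frac{\mathrm{AL}}{\text{query length}},$$

and merging guarantees CALP ≤ 1 even on pathological HSP sets. A
per-column brute-force recount serves as the test oracle. One-to-one
ortholog (COS) pairs require CIP ≥ 60 and CALP ≥ 0.70 — the boundaries
are inclusive, the common convention, frozen here for reproducibility — keeping for each query the best subject (highest
CIP, ties by CALP, then lexicographic subject id, for reproducibility).
Protein-level homologs use a 50 % identity threshold, with clusters
matching no proteome reported as putative species-specific.

Reference genes with no passing match are PAV (presence/absence
variants); a matched gene is a tandem CNV when some passing cluster hits
both the gene and a neighbour within one gene position on the same
chromosome. The neighbour is deliberately not required to win a
best-hit of its own: deterministic tie-breaking routes near-identical
tandem-copy clusters to the lexicographically smaller parent, so a
matched-neighbour requirement would miss every planted tandem. Copy
counts per reference gene are capped at 3 (the homoeolog triplet);
supernumerary matches are reported separately rather than silently
merged.

## Synteny and the virtual gene order

Anchors give each target gene the ordinal position of its ortholog
along a reference chromosome. `detect_blocks()` finds maximal runs of
anchors whose ranks are monotone in either direction with at most 5
missing anchors between neighbours (configurable; the gap default is a
choice, not a published value). `build_consensus_order()` builds the
virtual order by reference priority (rice > *Brachypodium* > sorghum >
maize in the canonical setting): the top reference fixes the backbone;
each lower reference interpolates its private genes between their
nearest already-placed neighbours, ordered within an interval by the
deciding reference's ranks and then gene id. "Most parsimonious" is
read here as inversion-minimising interpolation — one defensible
reading, recorded as such. Contradictory neighbour pairs send a gene to
an unplaced list (never dropped), and a lower-priority reference can
never reorder genes placed by a higher one.

## Duplicate-fate statistics

`classify_triplet_fate()` labels each gene from its detected copies:
`structural_loss` (fewer than 3 copies), `diverged_within_kinetic`
(grain-stage profiles differ), `diverged_between_tissues` (tissue-level
presence differs), `conserved` (three copies, identical everywhere).
Percentages follow the conventions of the numbers they reproduce:
small-panel (SSCP-style) rates round half-up to integers (43/79 → 54 %),
copy-histogram and paralog-retention rates round half-up to one decimal
(193/7158 → 2.7 %, 166/862 → 19.3 %), and concerted presence/absence
rates are *truncated* to one decimal (2600/6760 = 38.46 → 38.4,
2944/6760 = 43.55 → 43.5) — truncation is the only rule consistent with
both printed values, so it is frozen and exposed as `pct_trunc()`.

The gene-ontology bias test is a per-category 2×2 Pearson chi-square
(no continuity correction, closed form, checked against the reference
implementation to 1e-9) at a 1 % threshold with *no* multiplicity
correction — flagged categories are screening candidates for family-level
follow-up, not confirmatory claims. Zero-margin
categories are skipped with a warning.

Network enrichment counts the "extra" members of retained duplicate
pairs inside a pathway: 20 retained pairs among 170 starch-pathway
genes give 12 % enrichment and a reconstructed pre-duplication network
of 150 genes. The bundled `starch_network_example()` table is a
synthetic membership table planted with those marginals (the original
pathway table is not redistributed); the arithmetic, not the pathway
biology, is what the package computes.

Differential expression is the plain equal-variance two-group t-test
per gene, with genes at the extremes of pooled variance excluded before
testing (default quantiles 0.5 %/99.5 %, configurable — the exclusion
rule only says "too small or too large", so the quantiles are a package
choice) and Bonferroni control at 0.05. A homoscedastic-variance
protocol could also be read as a moderated pooled-variance test; the
plain test is implemented and the ambiguity noted. A power
consequence the tests document: at 3 vs 3 samples and 100 genes, a
planted shift must exceed ~8.6 pooled standard deviations to clear the
Bonferroni threshold (t quantile arithmetic), so the test suite plants
12-SD shifts.

## The temporal shuffling model

Literature observations — the percent of duplicates structurally lost
or expression-diverged at known duplication ages, from allohexaploid
wheat (1.5–3 My) out to ancient paleoduplications (150–200 My) — ship
as a plain-text fixture. `fit_curve()` fits
$y = \mathrm{clamp}(a + b\,\ln t,\, 0, 100)$ by weighted least squares
on interval midpoints, with weights $1/\max(h, 1)^2$ for percent
half-width $h$: tighter literature estimates count more, and the
1-point floor keeps point observations (half-width 0) at finite weight,
treating them as known to about printed precision. The pooled
("total") curve simply concatenates structural and functional points;
no pooling rule is published, so this and the weighting are
config-exposed (`weighted`, `min_halfwidth`).

`time_at_level()` inverts the unclamped form,
$t = \exp((y - a)/b)$, flagging extrapolation outside the observed time
range. Two cautions the code surfaces itself: the pooled curve puts
half-shuffling near 4 My and ~58 % at 10 My — consistent with "about
half within ten million years" as an interval property — but inverting
to 100 % extrapolates to many hundreds of millions of years, because a
logarithm saturates far too slowly to date the *completion* of
diploidization. Completion-time claims are therefore treated as
interval statements about the data range, never as a fitted quantity.

## Numerical and engineering choices

* All randomness flows from integer seeds; per-stage sub-seeds are
  derived arithmetically and kept under $2^{31}$.
* Ties are always broken deterministically (consensus bases by first
  placement, best hits by CIP/CALP/id, interpolation by rank/id).
* Interval arithmetic for HSP chaining uses `IRanges`; pairwise
  alignment uses `Biostrings`. The bundled k-mer-seeded local aligner
  (`align_sequences()`) exists so the pipeline can be exercised without
  an external aligner; it is not a production aligner and the homology
  module consumes standard 12-column tabular alignments from any
  source (`read_m8()` converts 1-based inclusive to 0-based half-open).
* Problem sizes in the shipped analyses and tests (tens of genes for
  assembly stages, 1,500 genes for parameter recovery, 1,000-case
  scoring fuzz) were chosen so each stage's sampling error is small
  relative to the effects being measured while the whole suite stays
  quick to run.
* The `analysis/` directory holds the numbered narrative drivers
  (simulate → cluster → homology → synteny → fate → temporal model);
  all computation lives in the package functions they call, so the
  same code paths are exercised by the tests and the acceptance
  script. These drivers are the intended command-line surface; no
  separate CLI binary is shipped.

## Known limitations

* Single-linkage clustering cannot separate haplotypes whose divergence
  is much below the overlap-identity threshold; homoeolog separation at
  realistic SNP densities relies on the coverage-based merged-homoeolog
  flag rather than on assembly-level separation.
* The CNV rule uses sequence/position evidence only; cytogenetic
  evidence is out of scope.
* Genome-scale published counts (tens of thousands of clusters and
  homologs) depend on the real read set and annotations and are used
  only as threshold and ratio provenance, never reproduced.
* `concerted_expression_rate()` compares binary presence profiles;
  quantitative co-expression is out of scope, as is microarray
  normalisation (expression truth is consumed directly).
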