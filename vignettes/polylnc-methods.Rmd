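---
title: "Methods: lncRNA origin and epigenomic dynamics in hybrid and polyploid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA origin and epigenomic dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`polylnc` analyses a four-genome design: two diploid parent genomes (A and
D), their F1 hybrid (whose reference is the concatenation of both parental
genomes), and an allotetraploid carrying both as subgenomes. The questions
it operationalises are:

1. Which assembled transcripts are lncRNAs, and of what kind (intergenic,
   antisense, intronic)?
2. Which lncRNA loci have syntenic homologs in the partner (sub)genome,
   and of those, how many are transcribed on both sides (ST) versus only
   one (SA)?
3. Which TE families underlie lncRNA loci, and do families distribute
   differently between ST and SA loci?
4. Does F1 lncRNA expression deviate from the additive (mid-parent)
   expectation more than coding-gene expression does?
5. Are expression changes at lncRNA loci coupled to local DNA methylation
   changes, and are lncRNA-overlapped TEs (LINEs especially) depleted of
   siRNA coverage and methylation?

All coordinates inside the package are 0-based half-open; GTF/GFF3
(1-based closed) and BED (0-based half-open) conventions are converted
only at the readers and writers, so interval arithmetic is uniform
internally.

# Classification of lncRNA candidates

Class codes mirror assembler semantics. A transcript is `u` when its exons
overlap no coding locus span; `x` when its exons overlap a coding exon on
the opposite strand; `i` when it lies entirely within a single intron on
the same strand. Two decisions close gaps the class codes leave open:

- An antisense transcript lying wholly inside an intron has no exon-exon
  overlap, yet it is antisense to the gene; it is classed `x`, reserving
  `i` for same-strand intronic transcripts.
- Transcripts with any sense exon-exon overlap are excluded
  (`sense_overlap`), including those that also overlap another gene
  antisense. Partial sense overlap is treated as evidence the fragment
  belongs to the coding transcriptome.

The filter chain — spliced length ≥ 200 nt, class in {u, x, i}, coding
score ≤ 0, no domain hit — is a pure conjunction, so its order is
irrelevant; a property test asserts this. Score 0 sits on the kept side of
the boundary. Transcripts lacking a coding-evidence record are kept (and
counted in a message): evidence is an optional input here, whereas the
original tool chain scored every transcript. After filtering, each locus
is collapsed to its single longest surviving isoform, ties broken by
transcript ID for determinism.

The built-in coding score is a deliberately simple stand-in for external
coding-potential tools, which are out of scope: it is positive iff the
longest ORF across six frames reaches 100 codons (ORFs open at the
sequence end count), scaled as `(codons - 100) / 100`. On random 500-nt
sequences it misfires at a few percent — in the synthetic runs a handful
of planted lncRNAs carry a chance ORF and are (correctly, by the rule)
discarded, and degenerate copies of coding exons are flagged as coding
more often than by chance. Both behaviours are visible in the filter log.

# Synteny and the ST/SA classification

Anchor genes are coding genes only; lncRNA hits never seed blocks.
Reciprocal best pairs require each gene to be the other's top hit by bit
score with E < 1e-10 in both directions (ties broken by E-value, then
subject ID). Chains are found by dynamic programming over gene ranks per
chromosome pair: a chain may step at most 25 ranks in either genome, with
a consistent direction in the partner genome (same or inverted); chains
with ≥ 5 anchors are reported best-first and each anchor belongs to at
most one block. The 5-anchor default follows the commonly used `-s 5`
setting; a 4-anchor variant appears in some syntenic-region definitions,
so the threshold is exposed as a parameter. An exhaustive enumeration
oracle checks the chains exactly for up to 10 anchors.

Placement of a genome-A lncRNA locus: find the block whose A-span contains
it; take its best passing hit on the block's partner chromosome inside the
block's B-span; label ST if the hit overlaps a transcribed B lncRNA locus,
SYN_PCG if it overlaps a coding exon, SA if homologous sequence is present
but nothing is transcribed there, NON_SYN if the locus is outside all
blocks or has no in-span hit. "Transcribed" adopts the expression
threshold used throughout: RPKM > 0.5 in at least one sample of the target
genome. Within-block coordinate transfer (reported as `placed_pos`) uses
linear interpolation between flanking anchor midpoints; span membership
uses the full block span, which is robust to interpolation error.

Because an ST pair is discovered from both comparison directions while an
SA locus appears once, the pipeline deduplicates ST calls to unordered
pairs before computing the SA fraction `n_SA / (n_SA + n_ST)`; this makes
the planted pair-level fraction (default 0.8) directly recoverable.
NATs and intronic lncRNAs are excluded before synteny analysis — their
partial overlap with coding genes would confound the SYN_PCG label.

# TE attribution and enrichment

Each locus is decomposed into strand-aware upstream-2kb, exon, intron and
downstream-2kb regions (flanks clipped at chromosome ends). Among TEs
overlapping a region kind by ≥ 1 bp, the TE with the greatest annotated
fragment length is attributed — one family per (locus, region). The
tie-break beyond length (leftmost start, then TE ID) is a determinism
choice. Composition tables are per-locus (each assigned locus contributes
one family), not per-bp of overlap; the longest-TE rule makes the
per-locus reading the natural one.

ST-vs-SA family enrichment uses the two-sided Fisher exact test on the
2x2 table (has family / lacks family x ST / SA). The effect size is
`log2((p_ST + 0.5/n_ST) / (p_SA + 0.5/n_SA))` — a half-count
pseudo-proportion guard per group, so empty cells yield finite ratios.
Raw p-values are the default decision rule (threshold 0.01), with
Benjamini-Hochberg q-values reported alongside.

# Expression dynamics

RPKM is `count * 1e9 / (spliced_length * library_size)`. The in silico
mid-parent mixes parental replicates 1:1 at the count level: each parent's
counts are rescaled to the mean parental library size, halved, summed and
rounded. Under equal depths this is algebraically identical to mixing
reads 1:1, and the mix RPKM equals the mean parental RPKM up to rounding —
both identities are tested. Replicates are paired by sorted sample order;
a mismatch in replicate count drops the excess with a warning.

The differential-expression test is a fully specified stand-in for
dispersion-aware frameworks (which remain the right tool for real data and
are deliberately out of scope): replicates are pooled after
median-of-ratios normalisation, and the p-value is the exact two-sided
binomial test of the pooled focal count against the pooled total with
success probability equal to the focal group's normalised depth share.
Fold changes use normalised group means with a 0.5 pseudo-count; all-zero
loci get p = 1 and log2FC = 0. Classes: Up (p < 0.01, FC > 2), Down
(p < 0.01, FC < 0.5), Equal (expressed, neither), NotExpressed; expressed
means RPKM > 0.5 in ≥ 1 member sample.

**Calibration.** Ignoring biological dispersion makes the pooled binomial
test anticonservative roughly in proportion to mu times phi (mean count
times NB dispersion). At the low-expression regime typical of lncRNA loci
— median ~3 reads per replicate near the RPKM 0.5 detection floor,
dispersion 0.1 — the empirical type-I error at alpha = 0.01 stays within
[0.002, 0.05] (measured on 20 x 2000-locus null simulations in the
acceptance suite). For abundant loci the p-value alone over-calls, and the
fold-change threshold is the practical guard; recovery tests at planted
4x / 0.25x effects show sensitivity ~1 and FDR ~0 at the joint
p-and-FC rule. Correlations between samples use Spearman's rho with
average ranks.

# Methylation, DMRs, and profiles

Weighted methylation of an interval is `sum(n_meth) / sum(n_total)` over
covered cytosines of one context — the coverage-weighted estimator, not a
mean of per-site ratios (a test distinguishes the two). Intervals without
coverage are masked, never zero-filled.

The DMR caller is a stand-in for externally derived DMR sets (an import
path for interval + context + direction tables is first-class, so the
caller is bypassable): per context, 100-bp windows stepping 50 bp with
≥ 4 covered cytosines in both samples are tested by Fisher's exact test on
pooled (methylated, unmethylated) counts; windows with p < 0.01 and
|delta| ≥ 0.1 merge when overlapping with the same direction, the merged
region keeping the minimum window p and a delta recomputed over its span.
On null methylomes the fraction of windows called stays below 2 x alpha
(the delta floor does most of that work).

DMRs associate to a lncRNA locus when overlapping its span ± 2 kb (the
same flank used for TE regions); a DMR overlapping several loci goes to
the greatest overlap, exact ties to all, flagged. The
methylation-expression correlation is Spearman by default (consistent with
the expression correlations; Pearson by flag) over a caller-chosen locus
subset — the pipeline uses differentially expressed lncRNA loci carrying a
DMR, falling back to all DE lncRNA loci when that subset is very small
(< 10).

Metaprofiles scale each feature body to `body_bins` equal fractions with
fixed-width flank bins, orient features 5'→3', and average per bin across
features with missing data masked. Features shorter than the bin count are
binned fractionally (each bin covering length/body_bins bp, fractional
base pairs weighted by coverage) — no bin repetition. A per-bp averaging
oracle checks the binning exactly. Multi-mapped sRNA reads are
down-weighted 1/n_mapped_loci in coverage tracks, so each read contributes
one unit of signal genome-wide.

# The synthetic study generator

`sim_config()` defaults define the study conditions; they are not tuning
knobs. Two diploid genomes share a collinear anchor-gene scaffold
(identical gene order and coordinates; sequence divergence by per-base
substitution, 3% for coding loci, 12% for lncRNA loci — lncRNA homologs
are markedly more diverged than coding homologs, as observed in
cross-genome comparisons). Per genome: 2 chromosomes of 200 kb, 40 anchor
genes (2 exons each, carrying a planted clean ORF so the coding filter has
signal), 120 lncRNA locus pairs. Category planting uses deterministic
counts: 55% of pairs syntenic, of which 80% SA (alternating which genome
transcribes), 5% homologous to a coding exon, the rest non-syntenic —
half placed outside the anchor span, half in-span without a homolog.
Two thirds of lncRNA pairs carry an overlapping TE, with LINE at 40% of
the lncRNA-overlapped mix although LINEs are ~1% of the genome; the
background TE landscape is Gypsy-dominated (~25% of the genome in total,
a scaled-down stand-in for a TE-rich plant genome).

Counts are negative-binomial (dispersion 0.05) at log-normal baselines
(lncRNAs lower than coding genes), two replicates per group. F1 and
allotetraploid means sit at the depth-normalised mid-parent multiplied by
the planted effect: 35% of lncRNA pairs are reprogrammed, split Up/Down,
with |log2| effects uniform on [1, 3] by default (tests of recovery at
fixed thresholds use fixed 4x / 0.25x effects). Methylomes are
per-cytosine binomial draws at Poisson coverage over cytosines located in
the actual simulated sequence, with baseline levels per feature class
(background < coding body < lncRNA body < lncRNA-LINE < lncRNA-TE < TE);
the F1 sample shifts levels over each reprogrammed locus (span plus its
planted TE) by a delta drawn from a Gaussian copula against the expression
effect, calibrated so the Spearman correlation equals the target (default
−0.6) via `rho_pearson = 2 sin(pi rho_spearman / 6)`, scaled by context
(CG 1, CHG 0.8, CHH 0.5 — monotone, so the rank correlation is preserved
per context). Small-RNA reads (20-25 nt, with a small out-of-range and
high-multiplicity tail so the filter is exercised) are sampled from a
per-bp weight landscape: TE body 8, TE flank 1.5, gene flank 3, gene body
0.8, background 0.3, with lncRNA-overlapped TEs depleted to 0.3x and
lncRNA-overlapped LINEs to 0.15x of the TE body weight.

Homology hit tables are derived from the simulated sequences themselves
(percent identity measured by position-wise comparison of the homologous
windows), with a few weak decoys to exercise best-hit selection; loci
planted without a homolog emit no hit. This replaces running an aligner,
which is an input in real use.

One seed drives everything through fixed per-stage child streams, so
adding a data type does not perturb the others; identical seeds give
byte-identical outputs.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: transcript assembly noise and fragmented
isoforms; realistic TE sequence structure (LTRs, target-site
duplications) and nested/fragmented insertions; read-level sequencing
artefacts (counts are drawn at locus level); genuine inter-chromosomal
rearrangements (blocks are clean by construction); bisulfite conversion
failure; and replication structure richer than two exchangeable
replicates. At the default TE density, TE flanks legitimately contain
neighbouring TEs, so the clean body-versus-flank recovery test uses a
sparse-TE configuration; the directional claims (siRNA depletion on
lncRNA-overlapped TEs, LINE below Gypsy methylation) are tested at the
default density.

# Problem sizes and determinism

The default configuration (2 x 200 kb per diploid genome, 120 lncRNA
pairs) keeps a full pipeline run around a minute on one core while leaving
every recovered quantity within its tolerance: SA fraction within ±0.05 of
0.8, methylation-expression rho within ±0.15 of −0.6, DE sensitivity
≥ 0.9 and FDR ≤ 0.1 at 4x effects. Unit tests use a one-chromosome 80-kb
configuration; the copula and the null calibrations are tested directly at
n = 500-2000 without genome simulation. All stochastic tests fix seeds.

# Known limitations

- The DE stand-in's p-values are trustworthy only in the low-count regime
  documented above; for real libraries use a dispersion-aware framework
  and feed the resulting classes into the downstream associations.
- The DMR caller is window-based with a fixed delta floor; imported DMR
  sets are preferred when available.
- Locus grouping for annotations lacking gene IDs merges same-strand
  exonic overlap transitively, which can over-merge read-through
  neighbours.
- SYN_PCG placement checks coding-exon overlap of the best in-span hit;
  locus-span overlap would be more permissive. Exon overlap was chosen as
  the stricter, better-defined criterion.
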