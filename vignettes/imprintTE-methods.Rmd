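---
title: "Methods: transposon-distributed binding sites and endosperm imprinting"
author: "imprintTE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transposon-distributed binding sites and endosperm imprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and scientific setting

The triploid endosperm carries two maternal genomes and one paternal
genome, and a subset of its genes is imprinted: expressed predominantly
from one parental allele (MEGs maternally, PEGs paternally). Type I
MADS-box transcription factors act in this tissue, and their
CArG-box-like binding motifs — canonical form CC(A/T)~6~GG — can be
carried and dispersed by RC/Helitron transposons, so that a single
ancestral motif-bearing element may seed binding sites across the
genome. This package implements the computational machinery needed to
study that system: binding-site definition from replicated ChIP peaks,
motif scanning and density statistics, permutation tests of TE overlap,
homology clustering of motif-carrying TE copies, allele-specific
chromatin profiling, and a ploidy-aware imprinting classifier. A
synthetic-data generator with planted truth supports parameter-recovery
validation of every stage.

All interval arithmetic uses the Bioconductor `GRanges` convention
internally (1-based, closed); BED (0-based half-open) and GFF3 (1-based
closed) are converted at the I/O boundary, so a single coordinate
convention holds everywhere and the BED semantics — touching intervals
do not overlap — are preserved exactly.

# Binding sites and target genes

Two biological ChIP replicates are reconciled by intersection: for
every overlapping pair of replicate-1 and replicate-2 peaks the shared
interval is emitted, and overlapping emissions are merged
(`commonPeaks()`). Intersection is the conservative reading of
"regions common to both replicates"; a union-based reading would admit
sequence supported by only one replicate. The per-replicate
reproducibility fraction (peaks overlapping the other replicate) is
reported alongside.

Sites are annotated to the nearest TSS from the site **midpoint**, with
orientation-aware signed distances (negative = upstream in the gene's
own orientation). The midpoint is the natural single-point anchor for
regions a few hundred bases wide whose motif density peaks centrally.
Feature classes are promoter (within 3 kb upstream, configurable),
gene body (midpoint inside the nearest gene), else intergenic. Target
genes are those with a site in the window 1.5 kb upstream to 0.5 kb
downstream of the TSS; both window boundaries are inclusive — the
one-base ambiguity this resolves is documented here and nothing
downstream depends on it.

# Motif scanning and density

The default motif is the CArG-box consensus `CCWWWWWWGG`. A 10-mer is
*perfect* when it belongs to the 2^6^-member consensus set and *nearly
perfect* when its minimal Hamming distance to that set is exactly 1
(one substitution away from some perfect sequence). Because positions
are independent, the distance to the set equals the count of positions
violating the consensus; the test suite cross-checks this identity
against explicit enumeration of all 64 perfect sequences. Both strands
are scanned; the CArG consensus class is closed under reverse
complement, so a genomic occurrence would otherwise be reported twice —
double-strand hits at identical coordinates are deduplicated to one
record (a choice the scanner documents rather than inherits, since
common scanners differ here). Windows containing `N` never match.

Motif density is occurrences per base of a region class, with each
occurrence assigned to the class containing its **start base**; this
makes densities exactly invariant under splitting a class into adjacent
sub-intervals. Classes are compared with 2×2 χ² tests of independence
on (motif bases, non-motif bases), without Yates correction by default
(available by flag).

# TE-overlap permutation test

The observed statistic is the fraction of binding sites sharing at
least one base with a TE feature. The null model shuffles a site set
with the identical length multiset into the promoter universe (3-kb
upstream spans of all genes, unclipped by default): each random site is
placed wholly inside one promoter chosen uniformly among promoters able
to contain it, at a uniform offset. Promoter choice is uniform per
promoter rather than length-weighted (promoters here are near-constant
3 kb, so the distinction is minor; a length-weighted mode would be the
natural extension). Containment within a single promoter is enforced —
allowing sites to cross promoter edges would leak null mass into
unannotated flanks.

The empirical p-value uses the add-one rule (r+1)/(n+1), the standard
Monte Carlo estimator that can never return 0; the z-score is
(observed − null mean)/null s.d., reported as `NA` when the null is
degenerate. With a fraction lattice of 1/n~sites~, ties between
observed and null values make the estimator mildly conservative; the
calibration experiment in the acceptance suite therefore uses 150
sites over 200 promoters (200 null datasets × 500 iterations), where
the rejection rate at α = 0.05 sits near 0.04 and p-values pass a
Kolmogorov–Smirnov uniformity check. The inner loop runs on plain
integer vectors (`findInterval` over merged feature intervals), which
is what makes tens of thousands of shuffles per test run affordable.

# Homology of motif-carrying TE copies

Pairs of motif-carrying sequences are aligned with full Smith–Waterman
local alignment under affine gaps, using BLASTN's nucleotide scoring
(match +2, mismatch −3, gap existence 5, extension 2; a gap of length
L costs 5 + 2L; `N` scores as a mismatch). Exhaustive dynamic
programming replaces BLAST's seeded heuristic: at desk scale the
optimum is affordable, seeding can only lose homologies, and the
biology is carried by the thresholds, not the search strategy. The
word-size parameters of the heuristic (7 intra-genome, 11
cross-species) are therefore documentation-only. Only the single best
local alignment per pair is evaluated; multiple HSPs jointly satisfying
a span rule are not considered.

A pair is homologous (intra-genome rule) when the aligned span on the
reference covers at least 9 of the 10 motif bases, the alignment is
longer than 30 columns, and identity exceeds 70% — all strict where
stated, and the acceptance tests probe each boundary (length exactly
30, identity exactly 70.0, coverage 8/10 all reject). Identity is
computed over all alignment columns with gap columns counting as
non-identical; the alternative denominator (shorter sequence length)
can only raise identity and would weaken the threshold. The
cross-species rule requires a reference span above 100 nt with identity
above 60%. Homologous pairs are merged into connected components;
cluster ids are deterministic (lexicographically smallest member).

# Allele-specific chromatin profiles

Signal tracks (bedGraph per parental allele) are quantified in 50-bp
bins across 2-kb windows centred on site midpoints. A bin's value is
the coverage-weighted mean of the track over the bin; bins without
coverage are missing, never zero-filled, and sites whose window would
cross a chromosome end are dropped and reported. Windows are not
strand-flipped by default (orientation-aware flipping is available),
since flank/centre archetypes are symmetric.

Sites are clustered on the total H3K27me3 matrix by k-means (k = 2),
with deterministic numbering: cluster 1 is the cluster with the higher
mean flank signal (outer quarters of the window), so labels are stable
across seeds. k-means uses Lloyd's algorithm with k-means++ seeding
and the best of 10 restarts under a fixed seed.

Gene-body scores average a z-scored track over each gene body.
Standardization is over all genome-wide bins of the track
(width-weighted mean 0, s.d. 1); external standardization constants
can be supplied where a reference construction differs — the exact
z-score construction of published allele-specific tracks is defined in
their source studies, so this package makes its own construction
explicit and configurable.

# Imprinting classification

Per replicate, the parental ratio is maternal/(maternal+paternal)
reads; replicates under 10 informative reads are excluded (the filter
threshold is configurable — it mirrors the conventional
lowly-expressed-gene filter rather than a rule specific to imprinting),
and surviving replicate ratios are averaged per gene and cross. The
biallelic expectation is maternal odds ω = 2 in 2x seeds (2m : 1p
genomes) and ω = 1 under 3x paternal excess (2m : 2p).

The four-fold deviation that defines MEGs and PEGs is applied on the
odds scale: MEG when odds ≥ 4ω (fraction ≥ 4ω/(4ω+1)), PEG when odds ≤
ω/4. This is the only reading that keeps both thresholds inside (0, 1)
for any expectation and treats the maternal and paternal directions
symmetrically; on the fraction scale, "four-fold more maternal" from
2/3 would exceed 1. The resulting thresholds are 8/9 and 1/3 in 2x,
4/5 and 1/5 in 3x. Boundaries are inclusive (≥/≤) for deterministic
tie handling. When both crosses are present, calls are cross-tabulated
per gene — the "is imprinting maintained under paternal excess?"
readout.

# The synthetic-data generator

`simulationConfig()` fixes the study conditions; one seed governs the
whole bundle byte-for-byte. What the generator emulates, and its
defaults:

* **Genome and annotation** — uniform-composition chromosomes (default
  1 × 3 Mb), 200 non-overlapping genes with ≥3-kb promoter spacing and
  random strands, and 300 TE copies of three superfamilies
  (120 RC/Helitron, 90 LTR/Gypsy, 90 DNA/MuDR), half of them placed in
  promoters. TE copies never overlap one another, so a planted motif
  belongs to exactly one copy and carrier flags are exact.
* **Planted motif family** — half of the Helitron copies carry a
  perfect CArG motif and descend from one 400-bp ancestral element
  mutated at 5% per base (motif bases spared), mirroring radiation
  from a single ancestral motif acquisition and giving the homology
  stage a recoverable family. Chance perfect-motif occurrences inside
  TE spans or promoters are mutated away so planted truth is exact;
  elsewhere the background composition is untouched.
* **Peaks** — 150 peaks of 150–400 bp; 70% are centred on the planted
  motif of a promoter Helitron (the biological signal; motifs sit
  100–1400 bp upstream of the TSS so targeting peaks are recoverable
  by the 1.5 kb/0.5 kb window), the rest fall uniformly in promoters.
  Replicate 2 shifts the shared core by up to ±25 bp and each
  replicate carries 10% private peaks — jitter of tens of bases and
  ~90% replicate agreement are typical of well-behaved ChIP
  replicates.
* **Allelic counts** — 150 expressed genes, 15% MEGs and 15% PEGs, two
  replicates per cross at depth 200–400. Maternal counts are
  beta-binomial with intraclass dispersion ρ = 0.02 (ρ = 0 is plain
  binomial; a separate `deterministic_counts` switch gives the exactly
  noise-free limit, where counts are rounded expectations, used for
  the 100%-recovery contract). Planted imprinted genes sit at 1.5
  times the four-fold threshold measured on the log-odds scale
  (odds = ω·4^1.5^): the fold-deviation is itself multiplicative, so a
  margin factor on it composes on the log scale.
* **Chromatin archetypes** — each profiled site (windows deduplicated
  so one locus has one chromatin state) is cluster 1 with probability
  0.5: maternal flank signal at baseline 0.2 + amplitude 2 with a
  500-bp depleted centre over a flat paternal background; cluster 2 is
  flat-depleted on both alleles. Gaussian bin noise has s.d. 1 — half
  the flank amplitude. CG-methylation tracks run at baseline 0.3 with
  a +0.3 paternal offset on MEG-associated sites, the
  hypomethylated-maternal-allele asymmetry seen at imprinted loci.

What the generator does **not** emulate: realistic nucleotide
composition or TE sequence models, read-level noise (FASTQ), mapping
bias between parental alleles, non-CG methylation contexts, or linked
placement of TEs and genes beyond the promoter construction. Passing
recovery tests therefore demonstrates the correctness of the
algorithms under the stated statistical model, not robustness to every
artefact of real sequencing data.

# Pipeline, seeds and problem sizes

`runPipeline()` executes simulate → common peaks → annotation/targets →
motif scan/density → TE-overlap permutation → homology clusters →
flanking-gene categories → allelic profiles → imprinting calls,
writing every stage's outputs, a manifest (package version, seed,
parameters, output list) and — when truth tables exist — a recovery
report (target recall and false-target rate, largest homology-cluster
fraction, signal-cluster adjusted Rand index, imprinting accuracy,
permutation p/z for the planted enrichment). The master seed fans out
as fixed offsets to per-stage child seeds, so any stage can be re-run
in isolation and reruns are byte-identical. Stage failures abort with
the failing stage named and a `FAILED` marker left beside the partial
outputs. The package is a library: the exported functions and
`runPipeline()` are the interface, and `scripts/acceptance.R` is the
reproducibility entry point.

Validation problem sizes, chosen as the smallest scales at which each
property is statistically meaningful: alignment oracle on 50 random
pairs ≤ 60 bp; scanning oracle on 100 kb; hypergeometric grid to
N = 30 and exact Mann–Whitney to group size 8; calibration on 200 null
datasets × 500 iterations (150 sites, 200 promoters); planted
3×-enrichment with 150 sites at 1000 iterations; homology recovery on
21 related plus 30 unrelated 300-bp sequences; imprinting recovery on
1000 genes; archetype recovery on ≥200 sites; end-to-end on the
default 200-gene configuration, run twice for byte-identity.

# Known limitations

* The common-peak rule is intersection-based; a replicate-anchored or
  union rule would give systematically wider sites and more targets.
* Nearest-TSS annotation considers genes on the site's chromosome and
  breaks exact distance ties lexicographically.
* The permutation null conditions on the promoter universe; it does
  not model genome-wide or circular shuffles.
* Percent identity includes gap columns; alignments are single-HSP.
* The imprinting classifier applies fixed ratio thresholds, not
  per-gene statistical tests; shallow genes are filtered, not modelled.
* k-means archetype clustering assumes two profile classes; more
  heterogeneous chromatin landscapes need larger k and external
  validation of cluster count.
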