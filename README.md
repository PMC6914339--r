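# imprintTE

Analysis toolkit for a regulatory-genomics question from the seed
endosperm: how does a MADS-box transcription factor come to control a
genome-wide network of imprinted and endosperm-development genes, when
its CArG-box-like binding motifs were scattered through the genome by
RC/Helitron transposons? The package re-implements the full desk-scale
analysis stack around that question — ChIP binding-site definition and
target calling, motif scanning and density statistics, TE-overlap
permutation testing, homology clustering of motif-carrying transposon
copies, allele-specific chromatin profiling, and ploidy-aware
classification of imprinted genes — together with a synthetic-data
generator that plants machine-readable truth, so every stage can be
validated by parameter recovery without any external download.

## What the package computes

**Binding sites and targets.** Peaks are called per replicate upstream
of this package; `commonPeaks()` keeps only regions supported by both
replicates (pairwise intersections, merged), `annotateSites()` assigns
each site to the gene whose TSS minimises the orientation-aware signed
distance from the site midpoint, and `callTargets()` calls a gene a
target when a site lies within 1.5 kb upstream to 0.5 kb downstream of
its TSS.

**Motifs.** `scanConsensus()` scans both strands for the CArG-box
consensus CC(A/T)<sub>6</sub>GG, classifying each 10-mer as *perfect*
(a member of the 2^6-sequence consensus set) or *nearly perfect*
(minimal Hamming distance to that set exactly 1), with palindromic
double-strand hits reported once. `motifDensity()` compares motif
density across genomic region classes with 2×2 χ² tests on the
proportion of motif bases.

**TE overlap.** `permutationTest()` measures the fraction of binding
sites overlapping each TE superfamily and compares it with a Monte
Carlo null in which a site set with the same size distribution is
shuffled uniformly into gene promoters (`shuffleSites()`); the
empirical p-value is (r+1)/(n+1) and a z-score is reported from the
null mean and s.d.

**Homology.** `localAlign()` computes optimal Smith–Waterman local
alignments under BLASTN-style scoring (match +2, mismatch −3, gap
existence 5, extension 2); `pairHomology()` applies the homology rule
(alignment covering ≥9 of the 10 motif bases, longer than 30 columns,
identity above 70%; cross-species profile: reference span >100 nt,
identity >60%), and `clusterPairs()` merges homologous pairs into
connected-component clusters.

**Imprinting.** The parental expression ratio of a gene is
maternal/(maternal+paternal) reads, averaged over replicates with ≥10
informative reads. The biallelic expectation is 2 maternal : 3 total
reads in 2x seeds and 2 : 4 under 3x paternal excess;
`imprintingThresholds()` applies a four-fold deviation on the
maternal:paternal odds scale, giving MEG/PEG thresholds of 8/9 and 1/3
(2x) and 4/5 and 1/5 (3x), and `classifyImprinting()` labels genes and
cross-tabulates 2x against 3x calls.

**Allelic chromatin.** `binSignal()` quantifies per-allele H3K27me3 or
CG-methylation tracks in 50-bp bins across 2-kb windows centred on
binding sites; `clusterSites()` separates flank-enriched/centre-depleted
from flat-depleted profiles by k-means; `geneBodyScore()` averages
z-scored signal over gene bodies; `methylationContrast()` compares
allele-specific methylation across MEG-, PEG- and
non-imprinted-associated sites with Mann–Whitney tests.

## Worked example

```r
library(imprintTE)

cfg <- simulationConfig(seed = 1, n_chrom = 1, chrom_length = 6e5,
                        n_genes = 40,
                        te_counts = c("RC/Helitron" = 30,
                                      "LTR/Gypsy" = 20, "DNA/MuDR" = 20),
                        peak_count = 40, n_expressed_genes = 30)
ann <- simulateAnnotation(cfg)
pk  <- simulatePeaks(ann, cfg)
bss <- commonPeaks(pk$rep1, pk$rep2)
bss
#> BindingSiteSet with 20 binding sites
#>   replicate peaks: 40 (rep1), 40 (rep2)
#>   reproducibility: 95.0% (rep1), 92.5% (rep2)
```

Twenty regions are supported by both replicates (overlapping peaks at
one locus merge into one site). Target calling and the TE-overlap
permutation test then recover the planted biology — peaks were placed
preferentially on motif-carrying promoter Helitrons:

```r
targets <- callTargets(annotateSites(bss, ann$genes))
length(targets)
#> [1] 16

prom <- promoterUniverse(ann$genes)
teBy <- as.list(split(GenomicRanges::granges(ann$tes),
                      ann$tes$superfamily))
permutationTest(bss, teBy, prom, nIter = 1000, seed = 2)
#>       feature observed null_mean null_sd      z        p
#> 1    DNA/MuDR     0.00    0.0474  0.0487 -0.974 1.000000
#> 2   LTR/Gypsy     0.00    0.0634  0.0542 -1.168 1.000000
#> 3 RC/Helitron     0.65    0.1530  0.0793  6.269 0.000999
```

65% of binding sites overlap an RC/Helitron copy against a null
expectation of 15% (z = 6.3, empirical p ≈ 0.001 at 1000 shuffles);
the other superfamilies show no enrichment. The imprinting classifier
applies the ploidy-aware thresholds:

```r
imprintingThresholds("2x")
#> ImprintingThresholds [2x]: expected 0.667, MEG >= 0.8889, PEG <= 0.3333
imprintingThresholds("3x_paternal_excess")
#> ImprintingThresholds [3x_paternal_excess]: expected 0.500, MEG >= 0.8000, PEG <= 0.2000

al <- simulateAllelicData(ann, pk, cfg)
calls <- classifyImprinting(parentalRatio(al$counts))
table(calls$label, calls$cross)
#>             2x 3x_paternal_excess
#>   biallelic 23                 22
#>   MEG        3                  4
#>   PEG        4                  4
```

`runPipeline(cfg, outDir)` runs all stages in order, writes every
stage's TSV/BED outputs plus a manifest, and — on synthetic data — a
recovery report scoring the run against the planted truth.

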