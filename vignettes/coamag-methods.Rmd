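---
title: "Methods: distance-guided coassembly planning and MAG evaluation"
author: "coamag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-guided coassembly planning and MAG evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coamag)
```

# The problem

Genome-resolved metagenomics reconstructs draft genomes (MAGs,
metagenome-assembled genomes) by assembling shotgun reads into contigs
and binning the contigs by composition and abundance. When many
samples are available, two design choices dominate the outcome: which
samples to *assemble together* (single assembly vs. coassembly), and
which samples' read mappings to use as abundance signal for *binning*
(single-binning vs. cobinning). Crossing them gives the four
strategies SASB, SACB, CASB and CACB. Coassembling similar samples
concentrates reads of the same organisms and helps recover rare
genomes; coassembling dissimilar samples mixes strains and fragments
assemblies. `coamag` implements the computational core of a workflow
that chooses coassembly sets *without prior knowledge*, from the
sequence content of the samples alone, and evaluates the genomes that
come back.

# Metagenomic distances from k-mer abundances

Each sample is summarized as a profile of canonical k-mer counts
(`countKmers`): every length-k window over A/C/G/T in every read adds
one to the count of the lexicographic minimum of the window and its
reverse complement, making counts strand-independent; windows
containing N are skipped rather than shifted. The default k = 21 is
the conventional size for comparative metagenomics — long enough that
almost all 21-mers are genome-specific, short enough to be robust to
sequencing error. k is exposed (11–31) because results depend on it.
A `minAbundance` filter (default 1, i.e. keep singletons) is exposed
but not imposed.

Two dissimilarities between profiles p and q are provided
(`abJaccardDistance`, `brayCurtisDistance`), both over the union of
k-mers with absent k-mers counting zero:

* abundance-weighted Jaccard:
  \(d_{ABJ} = 1 - \sum_w \min(p_w, q_w) / \sum_w \max(p_w, q_w)\)
* Bray–Curtis:
  \(d_{BC} = 1 - 2\sum_w \min(p_w, q_w) / (\sum_w p_w + \sum_w q_w)\)

The AB-Jaccard form is the default: it is a true metric (the triangle
inequality is property-tested on random profile triples to 1e-12),
which matters because the dissimilarities are subsequently embedded in
a hierarchical clustering whose merge heights should behave like
distances. Bray–Curtis is bounded and symmetric but not a metric and
is provided for comparison. Two empty profiles are at distance 0 by
convention (identity of indiscernibles, degenerate case).

`pairwiseDistances` assembles the full labelled matrix. Internally it
counts k-mers as 2-bit-packed 64-bit codes and merges sorted code
vectors per pair; the scalar functions operate on the named profiles
directly, and the test suite checks that both routes agree pair by
pair to 1e-12.

# Choosing coassembly sets

The distance matrix is clustered with Ward agglomerative clustering
applied directly to the dissimilarities (`wardCluster`). The
"ward.D2" convention (Lance–Williams update on squared
dissimilarities) is used: the matrix is non-Euclidean and no embedding
is attempted; D2 is the variant consistent with Ward's original
minimum-variance criterion. Merge ties are resolved by the standard
`hclust` implementation, which is deterministic for a given matrix, so
runs are reproducible across platforms.

The dendrogram is then cut at every k in [2, n-1]
(`findOptimalClustering`) and each partition is scored by the mean
silhouette width (`meanSilhouette`): per sample, s = (b - a)/max(a, b)
with a the mean distance to co-members and b the smallest mean
distance to another cluster; samples in singleton clusters score 0
(the common convention; the alternative of scoring them -1 would
penalize legitimate outlier samples). The chosen number of coassembly
sets is the k maximizing the mean silhouette, with ties broken toward
smaller k (fewer, larger coassemblies are cheaper and are favored when
the score cannot distinguish).

When the optimal partition is much finer than an external grouping one
wants to compare against, `findSuboptimalClustering` picks a
*suboptimal* solution of comparable size: among local maxima of the
silhouette curve (score at least its neighbours', endpoints compared
one-sided), the k nearest the target, ties toward higher silhouette
and then smaller k. This rule is a documented policy — "a comparable
cluster count" does not determine a unique procedure — and can be
bypassed by forcing k directly (`--suboptimal-k`).

# Strategy expansion

`planStrategy` turns a sample list (and, for coassembly, a
`CoassemblyPlan`) into explicit assembly units and (sample, unit)
mapping jobs. Single-binning maps only a unit's member samples back
onto it; cobinning maps *every* sample onto every unit, which is what
makes its cost quadratic: |jobs(SACB)| = N² and |jobs(CACB)| = N·G
exactly, property-tested by enumeration for N ≤ 20. "All metagenomes"
is read as all samples in the input manifest. The package plans but
never executes assembly or mapping — the emitted TSVs are the contract
for an external executor — which keeps the tool honest about which
computation is its own.

# Depth tables, detection, prevalence

`contigDepthTable` accumulates per-base coverage per (contig, sample)
from alignment intervals (0-based half-open; SAM/BAM input is
normalized via the CIGAR's reference span; secondary/supplementary
alignments are dropped by default and no mapping-quality filter is
applied unless requested) and reports the mean and *population*
variance of the coverage vector, the two statistics
composition+abundance binners consume. Contigs shorter than 1500 nt —
the conventional floor for contigs worth binning — are excluded. The
writer emits the `jgi_summarize_bam_contig_depths` column layout
(`contigName contigLen totalAvgDepth` then `<sample>.bam` /
`<sample>.bam-var` pairs) so the file feeds MetaBAT2 unchanged.

`genomeCoverage` computes, per genome and sample: breadth (fraction of
positions covered at least once), mean depth (aligned bases over
genome length) and mapped-read fraction (distinct mapped read ids over
the sample's read total; duplicate alignments of one read add depth
but count once for recruitment). A genome is *detected* in a sample
at breadth ≥ 0.3 (`detectGenome`); the boundary is inclusive because a
stated minimum of 30% reads as ≥, and the threshold is exposed.
`prevalenceAbundance` then reports per genome the number of samples
with detection and the cumulative abundance, the sum over samples of
the percentage of mapped reads divided by genome length. The
mapped-read denominator is per sample (not pooled), documented here
because either reading is defensible.

# Quality classes and dereplication

`classifyQuality` applies the standard bin-quality classes with strict
inequalities: HQ requires completeness > 90 *and* contamination < 5;
MQ requires completeness > 50 and contamination < 10; everything else
is LQ. A bin at exactly (90, 5) is therefore MQ. Only HQ and MQ bins
are MAGs, and only MAGs may enter dereplication.

`estimateAni` is an alignment-free ANI estimator built from windowed
k-mer containment: the smaller genome is tiled into non-overlapping
1-kb windows (trailing partial windows dropped; a window must hold at
least 2k bases), and for each window j is the fraction of its
canonical 16-mers found anywhere in the other genome. Under a uniform
substitution model a k-mer survives divergence p with probability
(1-p)^k, so E[j] = (1-p)^k and each mapped window's identity is
estimated as j^(1/k). Windows with j = 0 are unmapped; ANI is the
mean identity over mapped windows and the aligned fraction is the
share of mapped windows, measured on the smaller genome. The
estimator is validated against the *known realized substitution rate*
of simulated genome pairs (within 0.5 percentage points up to 10%
divergence), not against an external ANI tool. Random unrelated
genomes share essentially no 16-mers, so their aligned fraction
collapses to ~0 and they can never merge.

`dereplicate` joins two MAGs when ANI ≥ t over strictly more than 60%
of the smaller genome's bases, and takes connected components of that
graph (single linkage) as clusters — the simplest rule consistent with
a pairwise "considered duplicated if" criterion; t = 0.95 corresponds
to species-level and t = 0.99 to strain-level dereplication. Each
cluster's representative maximizes completeness − 5 × contamination (a
borrowed convention from dereplication tooling, not a measured
quantity), ties broken by larger genome then lexicographic id.

# The synthetic community generator

Every stage above is testable offline against
`generateClusteredDataset`, which plants known structure:

* genomes are i.i.d. random sequences at a chosen GC (no downloads;
  distance and clustering tests need composition contrast, not
  biological realism);
* genomes are split into disjoint per-group pools (plus an optional
  shared pool, default none);
* each *group* draws one log-normal base abundance vector with μ = 1,
  σ = 2 on the natural-log scale (the standard community-simulation
  parameterization); each *sample* multiplies that base by per-genome
  log-normal noise with σ_within = 0.5 and renormalizes. Samples of a
  group thus share composition up to moderate fluctuation, the way
  replicate metagenomes from one habitat do, while samples of
  different groups share essentially no k-mers. Fully independent
  per-sample draws at σ = 2 would make two same-group samples nearly
  as distant as two different-group samples (a single genome dominates
  each draw), destroying the within-group cohesion the planted
  structure is meant to provide — σ_within is the knob that moves
  between those regimes and 0.5 was fixed once as a realistic
  replicate-level fluctuation;
* reads are drawn with source genome ∝ abundance × length, uniform
  start and strand, and uniform substitution errors (default 0.5%, a
  typical short-read substitution rate). Indels are not simulated:
  at these rates they are irrelevant to k-mer distance behaviour and
  would complicate the exact read-origin ground truth.

All randomness flows through R's RNG under an explicit seed, so a
spec+seed pair reproduces byte-identical FASTQ and truth files.
`strainPanel` builds the dereplication fixture: unrelated species
ancestors, each with strains mutated at half a target pairwise rate
(pairwise divergences land in 1–3%, i.e. ANI 0.97–0.985: merged at
0.95, split at 0.99).

What passing these tests shows — and does not show: the generator
emulates abundance structure, group structure and substitution error,
but not real genome composition biases, repeats, strain mixtures
within a sample, or platform error profiles. Recovery of planted
groups demonstrates the machinery is correct, not that field samples
cluster this cleanly.

# Numerical and scale choices

* k-mer codes are 2-bit packed; the whole-matrix path stores codes in
  doubles (exact for k ≤ 26) and sorts per-profile, merging per pair.
* Distances are clamped to [0, 1] and symmetrized to absorb float
  round-off before validity checks; depth tables are written with 10
  significant digits so round-trips are lossless at test tolerance.
* Degenerate inputs: two empty profiles → distance 0; a k larger than
  every read → empty profile with a warning; a single cluster has no
  silhouette (error); n = 2 samples cannot be swept (error).
* Test problem sizes: the default community is 12 samples in 3 groups,
  20,000 × 150 bp reads per sample from 100-kb genomes (~3 Mbp per
  sample, a scaled-down metagenome). The 100-replicate recovery sweep
  uses 3–8 groups, 12–40 samples and 3,000-read samples from 30-kb
  genomes; the default-scale community is exercised end to end in the
  smoke test and the acceptance script.

# Limitations

* The ANI estimator's aligned fraction is k-mer containment per
  window, not an alignment; on genomes around the detection limit of
  containment (divergence ≳ 15%) both ANI and aligned fraction decay
  together.
* Single-linkage dereplication can chain: A–B and B–C links merge
  A and C even if their direct ANI is below t. At the thresholds and
  panel divergences used here chaining is the intended species-level
  behaviour, but pathological chains are possible in principle.
* Exact in-memory k-mer counting targets desk-scale data; terabyte
  inputs would need disk-based or sketched counting, which the
  operation contract permits provided the metric properties still
  hold.
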