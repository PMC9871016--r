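---
title: "Methods: mitochondrial gene order, codon usage and polycistronic transcription"
author: "mitorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial gene order, codon usage and polycistronic transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorder)
```

# Scope

Metazoan mitochondrial genomes carry an almost fixed gene set — 13
protein-coding genes, two rRNAs and (usually) 22 tRNAs — but arrange it
very differently across phyla.  `mitorder` provides the statistical
machinery to ask what those rearrangements do: how conserved gene
*order* is within and between taxa, whether codon usage tracks the
mtDNA-encoded tRNA repertoire, and whether strand-switch points between
gene blocks behave like boundaries of polycistronic transcription
units.  Every analysis consumes either a tabular interchange format
(the "genome table") or plain coverage/read tables, and every analysis
can be exercised end to end on synthetic data with known ground truth.

# Gene-order algebra

A gene order is a signed circular permutation: symbols with strand
signs, closed into a ring.  Two conventions drive everything else:

* **Anchoring.**  Circular records start at an arbitrary position and
  may be annotated from either strand, so orders are canonicalized by
  rotating the molecule until the anchor gene (`ND1` by default, being
  nearly universal) comes first on the forward strand; if the anchor is
  annotated on the reverse strand the whole order is
  reverse-complemented first.  Rotations and reflections of the same
  molecule therefore map to one canonical string.
* **Breakpoint distance.**  The distance between two orders is the
  number of signed adjacencies of one order absent from the other,
  after restricting both to their shared gene set.  An adjacency
  `(x, y)` equals its reading from the other strand `(-y, -x)`.  On
  equal content this is symmetric with zero diagonal.  Unequal content
  (e.g. cnidarians lacking most tRNAs) is handled by intersecting the
  symbol sets per pair; orders with duplicated symbols are excluded
  upstream, because breakpoint distance on multisets is ill-defined.

Cluster statistics reuse the same canonicalization: a cluster (a
contiguous signed run of genes) is identified with its
reverse-complement, windows may wrap past the anchor on circular
molecules, and ties between equally prevalent clusters break
lexicographically so results are deterministic.

The *alternating gene-block* classifier drops tRNAs, merges runs of
co-oriented genes circularly, and calls an order alternating when there
are at least two blocks and every block holds at least two genes (both
thresholds are arguments; "continuously alternating" is not a
quantified notion, so the defaults are the smallest values that
exclude single-gene strand islands such as the chordate `ND6`).  The
package ships `human_like_order()` (one forward block plus a lone
reverse gene — not alternating) and `drosophila_like_order()` (blocks
of +7/−3/+2/−3 non-tRNA genes — alternating) as reference regimes.

# Genome-architecture (AR) rate and its permutation test

For a taxon with `N_AR` distinct anchored order strings among
`N_mtDNA` organisms,

$$AR = \frac{N_{AR} - 1}{N_{mtDNA} - 1} \cdot 100 ,$$

0 for a fully conserved taxon, 100 when every organism is unique.  To
compare taxa of very different sizes, each class with at least 20
organisms is subsampled: 21 organisms at a time, 10,000 times, giving
an *observed* AR-rate distribution; the *expected* distribution
repeats the draw after shuffling class labels across the pooled
organisms, which is equivalent to drawing the subsample from the
global architecture pool.  The class is scored by the two-sided
empirical tail probability of the observed mean within the expected
distribution, with the add-one correction $p = (b+1)/(m+1)$ (never
exactly zero), Bonferroni-corrected across classes.

Two properties of this statistic matter for interpretation and are
easy to miss:

* Averaging the observed distribution makes the statistic concentrate
  on the *class-conditional* expectation.  When classes are much larger
  than the subsample, that expectation varies between classes far less
  than a single subsample draw does (the variance ratio is roughly
  `subsample / class size`), so under a true null the test is
  conservative.  Calibration studies in this package therefore use
  exchangeable classes of sizes 22–24, just above the subsample, where
  the observed statistic retains nearly the full between-draw variance;
  there the measured type-I error sits near 0.04–0.05.
* The rate of a subsample is a discrete quantity.  A pool with many
  moderately frequent architectures (the calibration studies use a
  Zipf-weighted pool of 200 types) keeps the discreteness mild; pools
  with a handful of architectures make the two-sided tail p visibly
  staircase-shaped.

# Codon usage versus the mt-tRNA repertoire

Coding sequences are admitted when a valid initiation codon for the
taxon's NCBI mitochondrial translation table opens the frame and a
STOP closes it; because mitochondrial STOPs are often completed by
polyadenylation, up to two `A` bases are appended before rejecting a
sequence.  Relative synonymous codon usage for codon $c$ of amino acid
$a$ is

$$RSCU(c) = \frac{o_{ac}}{\frac{1}{k_a}\sum_{c' \in C_a} o_{ac'}},$$

so uniform usage gives 1 and each amino acid's values sum exactly to
its degeneracy $k_a$ — an invariant the test suite checks to machine
precision.

Which codons count as "mtDNA codons" is decided from the tRNA
anticodons under a configurable wobble model.  Each codon is assumed
to be read by at most one tRNA.  The default (*superwobble*) reads a
wobble-U tRNA as covering purine-ending codons, or the whole box when
it is the sole isoacceptor of a four-fold degenerate box; wobble G
covers pyrimidine-ending codons; wobble A and C pair strictly.  This
reproduces the classical vertebrate families (tRNA-Leu(TAA) → TTR,
tRNA-Leu(TAG) → CTN, tRNA-Ser(GCT) → AGY, tRNA-Ser(TGA) → TCN).
Stricter presets (`twofold`, `strict`) are available because wobble
rules across metazoans are genuinely uncertain; conflicts between two
tRNAs claiming one codon resolve in favor of the exact Watson–Crick
match and otherwise raise an error rather than guessing.

The bias test pools, per amino acid and phylum, the per-organism RSCU
values of recognized codons against those of unrecognized codons
(amino acids qualify only with at least one codon on each side), uses
a two-sided Mann–Whitney test, adjusts with Benjamini–Hochberg within
the phylum, and calls a direction only at $q < 0.05$.  Pooling is per
organism rather than per gene: organisms are the exchangeable unit
across a phylum, and per-gene pooling would weight organisms by gene
count.

Because strand- and position-specific base composition can mimic codon
preference, a filtration step assigns each codon to the strand whose
genes use it most, finds the most prevalent base per (strand, codon
position), removes every codon carrying that base at that position on
its assigned strand (ties remove all tied bases, logged), and re-runs
the test on the survivors.  On planted-skew simulations the filtration
may remove an amino acid from testability but never reverses a
direction call.

# Junction read density: SSJ versus DSJ

If precursor transcripts are polycistronic, reads should span the
junctions *inside* a transcription unit but not junctions where
transcription terminates.  For each pair of neighboring genes
(excluding the pair that wraps across the control region) a counting
window is centered on the junction, with total length capped at 95% of
twice the sample's mean read length so that only junction-straddling
(precursor-derived) reads can be wholly contained; when the intergenic
region exceeds twice the read length the window splits into two
gene-edge windows whose counts are summed.  Junctions are typed SSJ
(same strand) or DSJ (different strands).  Counting is
strict-containment and discards reads contained in two different
features; strand is ignored, matching unstranded libraries.  Values
are normalized as

$$\frac{reads}{reads_{total} \cdot length} \cdot 10^9$$

for genes and junctions alike, and log-transformed as
$\log_{10}(x + 1)$ (base and pseudocount are a package choice).

Three quality filters precede testing: organisms need at least five
samples; junctions are dropped per sample when either flanking gene
falls below the sample's mean gene expression minus two standard
deviations; samples are dropped when more than half their junctions
have zero coverage (the signature of poly-A-selected libraries, which
deplete precursors entirely).  Per organism, DSJ and SSJ values pooled
over samples are compared by a two-sided Mann–Whitney test (exact
where sample sizes permit), Bonferroni-corrected across organisms,
with Cohen's d (pooled SD, negative for reduced DSJ) as effect size.
The association between alternating-block organization and significant
DSJ reduction is summarized in a 2×2 table tested by chi-square — the
statistic is reported both with and without the Yates correction, as
the two can differ noticeably at these sample sizes and neither is
privileged.  A motif-screening helper keeps motifs that occur within
500 bases of a DSJ (circular distance) in at least 80% of species,
boundary inclusive.

# TIS/TTS detection from nascent-RNA coverage

Transcription initiation and termination sites appear in
strand-specific nascent-RNA (PRO-seq-style) coverage as sharp steps.
Position $i$ is an initiation candidate when the mean of the 200-bp
upstream window falls below $sf$ times the mean of the combined 700-bp
window while the 500-bp downstream window exceeds the combined mean;
termination mirrors the condition.  The scaling factor multiplies the
*low* side of the step, which makes smaller factors strictly harder to
satisfy and candidate sets nested along the grid 0.9, 0.85, …, 0.05;
the detector selects the smallest grid value that still yields
candidates.  Peaks and valleys are optimized separately (per strand
and site kind): on a noisy baseline the valley condition intrinsically
needs a larger factor than the peak condition, and a single shared
factor would silently discard all terminations — the main numerically
delicate choice in this module.

Candidates within 100 bp chain into one aggregate, represented by the
maximum-coverage position (peaks) or minimum-coverage position
(valleys), ties resolving to the earliest position in strand
orientation.  Each representative receives the confidence score

$$\frac{\overline{cov}_{ds,250}}{\overline{cov}_{ds,250} + \overline{cov}_{us,50}}$$

for initiations and its complement for terminations — exactly 1 for a
perfectly sharp site, undefined (candidate discarded) when both
windows are empty.  Sites of one kind and strand within 100 bp across
samples merge at the confidence-weighted mean position.  Circular
genomes are handled by wrapping the scan windows; the
`extend_circular()` helper additionally supports the prepend-the-tail
convention used when reads are mapped against a linearized reference.
On linear tracks, positions lacking a full window are skipped rather
than padded.

# The synthetic-data generator

`simulation_spec()` fixes the study conditions; the generators are
first-class, seeded, and emit ground truth alongside the data:

* **Gene orders** evolve from a 37-gene vertebrate-like ancestor by
  Poisson-distributed translocations, reverse translocations,
  inversions and tandem-duplication-random-loss events (duplicate a
  segment, then randomly drop one copy of each duplicated gene, which
  preserves content), with class founders so diversity is structured
  by taxonomy.
* **Coding sequences** draw codons with probability proportional to a
  skew factor (default 2) for tRNA-recognized codons, so a two-codon
  amino acid has expected RSCU $2s/(s+1)$ versus $2/(s+1)$ — the
  closed form the tests check.
* **Junction reads** (100-base reads, 5,000 per sample, half mature)
  come from precursor transcripts that either read through the whole
  strand (`two_polycistrons`, the human-like regime) or stop at block
  boundaries with a 10-fold read-through depletion across DSJs
  (`block_terminated`, the Drosophila-like regime), plus gene-confined
  mature reads.
* **Coverage tracks** are piecewise-constant transcription units
  (depth 50 against a fivefold-lower background in the recovery
  studies) with per-position Poisson noise and circular wraparound.

What the generator does *not* emulate: sequence evolution, tRNA
structure, mapping artifacts, over-dispersed library noise beyond the
optional negative-binomial switch, or length heterogeneity of real
genes.  Passing tests therefore demonstrate that the statistical
machinery recovers planted structure under idealized noise — not that
any particular biological dataset will behave as cleanly.

# Problem sizes and reproducibility

The recovery and calibration studies run at sizes chosen to make their
estimates statistically meaningful while staying comfortably
desk-scale: exhaustive oracle comparison over all 50,360 signed
circular permutations of up to six genes; 1,000 random RSCU tables;
200 null replicates (400 permutation iterations each) for type-I
error; 100 replicates each for codon-bias power, both transcription
regimes of the junction analysis, and TIS/TTS recovery on 16-kb
circular genomes.  All randomness flows from a single integer seed;
rerunning any pipeline or script with the same seed reproduces outputs
byte for byte.

# Known limitations

* Breakpoint distance is the only rearrangement metric; no
  event-parsimony (translocation/inversion counting) distances are
  computed, and no ancestral orders are reconstructed.
* Genomes with duplicated gene symbols are excluded from order-level
  statistics rather than modelled.
* The wobble presets bracket, but cannot resolve, true codon–tRNA
  recognition in lineages with heavily modified tRNAs.
* The junction analysis assumes unstranded libraries by default and
  pools samples within an organism; a stranded mode exists but
  per-sample meta-analysis does not.
* The AR permutation p-value is conservative for classes much larger
  than the subsample (see above); ratios remain interpretable, and the
  Bonferroni correction compounds the conservatism.
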