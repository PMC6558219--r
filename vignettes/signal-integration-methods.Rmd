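---
title: "Methods: signal integration and STAT1/p65 co-binding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal integration and STAT1/p65 co-binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The biological question

Interferon (IFN) priming followed by TLR4 activation (LPS) induces many
pro-inflammatory genes more strongly than the sum of the single stimuli —
*signal integration* (SI). Mechanistically this is attributed to
STAT1-containing complexes (GAF homodimers at GAS elements, ISGF3 at ISRE
elements) co-binding with NF-κB (p65) at κB sites that sit tens to a few
hundred base pairs away, in both promoters and distal regulatory regions.
`sicobind` implements the computational side of that analysis: calling SI
genes from replicate RNA-seq counts, locating GAS/ISRE/NF-κB motifs,
intersecting them with STAT1 and p65 ChIP peaks, classifying genes into
single versus co-binding modes, and quantifying cross-condition overlap
and binding geometry — together with a seeded simulator that generates
data with known planted structure so every step can be validated end to
end.

## Expression model

Counts are normalized by **median-of-ratios** size factors: for sample
$j$, $\hat s_j = \mathrm{median}_i \; c_{ij} / (\prod_k c_{ik})^{1/m}$
over genes with all-positive counts. No pseudo-reference fallback is
applied; a matrix without such genes is an error. This estimator assumes
most genes are not differentially expressed — which is also why the
simulator plants effects in a minority (28%) of genes.

A gene counts as **expressed** in a cell type when its replicate-mean
normalized signal exceeds 8 (strictly) in at least one condition of that
cell type. The cutoff is applied per cell type and per condition rather
than to single samples: this permissive reading keeps genes induced from
a silent baseline (the Nos2 pattern) while still removing noise-level
genes. **Fold change** for a treated condition is
$(\bar x_t + \varepsilon) / (\bar x_c + \varepsilon)$ over replicate
means, with a symmetric pseudocount $\varepsilon = 0.5$ so that
induced-from-zero genes get a finite FC without reordering genes. A gene
is **up-regulated** at FC ≥ 2 (the boundary is configurable to strict
`>`; the two conventions differ only at exactly 2, and the inclusive
reading is the default).

The **SI statistic** is deliberately simple and strict:
$\mathrm{SI} \iff \mathrm{FC}_{\mathrm{IFN+LPS}} >
\mathrm{FC}_{\mathrm{IFN}} + \mathrm{FC}_{\mathrm{LPS}}$.
The packaged top-30 fold-change tables (one per IFN type, with reference
flags) are kept as a standing regression test of this rule; it reproduces
their flag sets exactly (25/30 and 26/30 flagged).

Cross-cell-type commonality is a three-set Venn partition over the
per-cell-type up lists. Two **overlap percentage** conventions are
provided because published overlap figures in this analysis family
back-solve to different denominators: `jaccard`
($100|A\cap B|/|A\cup B|$, used for list-versus-list comparisons) and
`sum` ($100|A\cap B|/(|A|+|B|)$, used for per-mode overlaps). Gene-set
enrichment is an upper-tail hypergeometric test against a user-supplied
GMT collection with a 0.05 flag threshold; no multiplicity correction is
applied, matching common practice for descriptive term lists.

## Motif scanning: two dialects

Both dialects scan both strands and report reverse-strand hits in
forward coordinates; `N` bases score as background (0 contribution to a
log-odds score; the mean column probability in the similarity score).

**Genome-wide log-odds.** $s(w) = \sum_i \ln p(b_i, i)/q(b_i)$ with a
uniform background and natural log — the convention under which the
per-class motif score thresholds (MST: GAS 6, ISRE 6, NF-κB 7) are
interpreted; the log base is exposed because score scales differ between
tools. PWM probabilities carry a 1e-3 pseudocount by default so absent
bases stay finite while consensus scores remain within numerical noise
of the closed form $L \ln 4$ for a degenerate matrix. Overlapping hits
are all reported; downstream classification needs only presence.

**Promoter matrix similarity.** Within the strand-aware −950/+50 bp TSS
window, the raw probability sum $r(w) = \sum_i p(b_i, i)$ is min-max
normalized with per-column maxima/minima, so the consensus scores exactly
1 and the per-column minimum exactly 0. The exact formula used by
webserver promoter scanners is not published; this min-max dialect
reproduces the [0,1] semantics under which the 0.85 (GAS/ISRE) and 0.90
(NF-κB) thresholds are stated, and is documented here as a dialect, not a
re-implementation. A class is present for a gene if **any** matrix of
that class has at least one hit in the window (several published matrix
ids map to one class; requiring all of them is the other defensible
reading, and "any" was chosen as the weaker assumption).

For a minus-strand gene the window is the mirrored stretch
[TSS−50, TSS+950) in forward coordinates; windows are clipped at
chromosome ends.

## ChIP integration

Interval algebra (intersect, subtract, merge) uses half-open 0-based
coordinates throughout, with touching intervals coalesced by merge.
A motif hit is **occupied** only when fully contained in a peak of the
matching factor (GAS/ISRE → STAT1, NF-κB → p65) from the *same*
condition; partial overlap and factor mismatches never count. Whether
hits should be allowed to pair with peaks called in other conditions is
not specified by the source analysis; same-condition matching is the
stricter choice and is what the simulator's schedule emulates.

Occupied sites are annotated to the **nearest TSS** by absolute distance
(sign flipped on minus-strand genes so positive means downstream), with
ties broken lexicographically by gene id, and discarded beyond ±100 kb.
Each site midpoint is then assigned one of seven genomic categories with
fixed precedence: promoter/TSS (−1 kb/+100 bp) > TTS (±100 bp) > 5′UTR >
3′UTR > exon > intron > intergenic. The source analysis names the seven
categories but no precedence; the order above resolves the rare overlaps
deterministically, and the TTS window mirrors the promoter's +100 bp by
symmetry.

A gene's **binding mode** for a combined-treatment condition is the set
of motif classes with ≥1 occupied annotated site, written in canonical
GAS/ISRE/NF-κB order; genes with several co-binding regions contribute
the union of their sites to a single gene-level mode. Mode overlap
between the two combined conditions is reported per mode with the sum
denominator (jaccard alongside).

**Summit distances** are signed p65-minus-STAT1 distances to the closest
p65 summit per STAT1 summit, histogrammed over ±1000 bp in 25-bp bins;
out-of-range distances stay in the distance list but not the histogram.

**Occupancy clustering**: RPKM per merged peak region and per sample
(reads in region / region kb / million total reads), k-means on
log2(RPKM+1) with k = 10 by default. Base-R `kmeans` (Lloyd, ≤300
iterations) is run from a deterministic farthest-point initialization
(first center drawn under the configured seed), and an emptied cluster
is re-seeded from the row farthest from its center — k-means is
otherwise not reproducible, and cluster *labels* are only meaningful
within one run. The RD matrix holds depth-normalized tag counts in 25-bp
bins over ±1000 bp around region centers.

## The simulator

`simulate_study()` generates, under one integer seed (byte-identical
outputs per seed):

* a uniform-background genome (2 × 4 Mb) with 300 genes on a fixed grid,
  each gene owning a disjoint ±10 kb motif territory so nearest-TSS
  annotation is unambiguous;
* one of eight planted modes per gene (72% none; 4% each of GAS, ISRE,
  NFKB, GAS-ISRE, GAS-NFKB, ISRE-NFKB, GAS-ISRE-NFKB), written into the
  sequence as PWM consensus strings — consensus planting guarantees
  scanner detectability at the stated thresholds without tuning — half
  in promoters, half distal (2–10 kb); composite groups spaced so every
  pairwise midpoint distance is uniform within 38–264 bp, the range
  reported for composite GAS/NF-κB and ISRE/NF-κB sites;
* negative-binomial counts (dispersion 0.05, baseline 100 × 2^U(−1,1),
  planted size factors U(0.7, 1.3)) for 3 cell types × 6 conditions × 3
  replicates. STAT-class genes respond to both IFNs with +3 log2 units,
  NF-κB-class genes to LPS with +3; 80% of motif-bearing genes share
  their effects across all three cell types, the rest respond in one.
  SI genes (40% of the shared core) get the super-additive combined mean
  $(2^a + 2^l) \cdot 2^{2}$; non-SI responders get the *sub-additive*
  combined response $0.9 \times \max(2^a, 2^l)$ — the pattern the
  published non-SI rows actually show, where the combined FC sits just
  below the dominant single-arm FC. This makes the planted SI flag
  strictly consistent with the SI inequality in expectation on both
  sides;
* STAT1 peaks over GAS/ISRE motifs in IFN and IFN+LPS conditions and p65
  peaks over NF-κB motifs in LPS and combined conditions, plus — with the
  `sequential_recruitment` flag (default on) — p65 at composite sites
  under IFN alone, emulating STAT1-complex recruitment preceding p65.
  Summits sit on motif midpoints (jitter 0 by default); every peak
  contains its motif. Coverage is Poisson: flat background (0.5 tags per
  25-bp bin) plus a Gaussian pile (σ = 75 bp, 300 tags) under each
  scheduled peak, binned at 25 bp over peak neighborhoods.

What the simulator does **not** emulate: read-level artifacts, GC and
mappability bias, replicate-level peak irreproducibility, correlated
background (it is Markov-0 uniform, which makes scanner false-positive
rates analytically predictable), overlapping gene territories, and
motif instances weaker than consensus. Passing recovery tests therefore
demonstrates the pipeline's correctness on data satisfying its own
assumptions, not robustness to the full messiness of real ChIP-seq.

## Numerical and design choices

* Coordinates are uniformly 0-based half-open internally; 1-based
  appearances are I/O formatting only.
* TSS of a minus-strand gene is span end − 1 (a point coordinate);
  six-column peaks get the interval midpoint as summit.
* Degenerate inputs: empty intervals, ragged PFMs, all-zero PFM columns
  with zero pseudocount, non-integer counts, and missing sample-sheet
  columns are rejected with the offending line or label named.
* Problem sizes were chosen so the full default simulation-and-recovery
  cycle (300 genes, 8 Mb genome, 54 libraries, 12 coverage tracks)
  completes in well under two minutes on one core; unit tests use a
  60-gene, 3 Mb variant of the same configuration.
* The fold-change boundary (≥ vs >), log base, MSTs, similarity
  thresholds, windows, k and all seeds are configuration, not constants,
  so sensitivity to each convention can be probed directly.

## Known limitations

SI calling inherits the noise of ratio statistics: for genes whose
combined response is dominated by one arm, the margin between
"sub-additive" and "super-additive" is a few percent of the FC and
replicate noise can flip individual genes. The hypergeometric enrichment
assumes exchangeable genes (no length or expression bias correction).
Mode classification reports what is occupied within ±100 kb; it does not
attempt enhancer-promoter assignment beyond nearest-TSS. The similarity
dialect is one member of a family of affine PWM scores; absolute
similarity values are comparable only within a matrix.
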