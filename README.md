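# sicobind

Signal integration and STAT1/NF-κB co-binding analysis for RNA-seq and
ChIP-seq.

Interferon (IFN) "priming" followed by TLR4 stimulation (LPS) induces many
pro-inflammatory genes super-additively — a pattern called **signal
integration (SI)** — and the mechanism is attributed to STAT1-containing
complexes (GAF at GAS elements, ISGF3 at ISRE elements) co-binding with
NF-κB (p65) at closely spaced composite sites. `sicobind` is for
computational biologists analyzing such paired expression + binding
experiments (vascular and immune cells treated with IFNα/IFNγ and/or LPS
being the motivating design): it turns replicate count tables, genomes,
gene models, peak sets and motif matrices into SI calls, occupied-site
catalogs, binding-mode classifications and occupancy clusterings — and it
ships a seeded multi-omic simulator with planted ground truth so the
whole pipeline is testable end to end.

## The statistics at the core

* **Normalization**: median-of-ratios size factors,
  `s_j = median_i c_ij / (Π_k c_ik)^(1/m)` over all-positive genes;
  expressed filter: replicate-mean normalized signal > 8 in ≥ 1 condition
  per cell type; fold change `FC = (x̄_t + ε)/(x̄_c + ε)`, ε = 0.5;
  up-regulated at FC ≥ 2.
* **SI statistic** (strict super-additivity):
  `SI ⇔ FC(IFN+LPS) > FC(IFN) + FC(LPS)`.
* **Motif scanning**, two dialects: genome-wide log-odds
  `s(w) = Σ_i ln p(b_i,i)/q(b_i)` against motif score thresholds
  (GAS 6, ISRE 6, NF-κB 7), and min-max matrix similarity
  `(r − r_min)/(r_max − r_min)` in the −950/+50 bp promoter window
  against 0.85 (GAS/ISRE) and 0.90 (NF-κB).
* **Binding modes**: a motif hit is *occupied* when fully inside a peak
  of the matching factor (GAS/ISRE → STAT1, NF-κB → p65) in the same
  condition; occupied sites annotate to the nearest TSS within ±100 kb
  and to seven genomic categories (promoter/TSS −1 kb/+100 bp, 5′UTR,
  3′UTR, exon, intron, TTS ±100 bp, intergenic); the gene's mode is its
  set of occupied classes, one of GAS, ISRE, NFKB, GAS-ISRE, GAS-NFKB,
  ISRE-NFKB, GAS-ISRE-NFKB.
* **Geometry and occupancy**: signed STAT1-to-nearest-p65 summit
  distances histogrammed over ±1 kb in 25-bp bins; RPKM occupancy per
  merged peak region clustered by deterministic k-means (k = 10).

See `vignettes/signal-integration-methods.Rmd` for assumptions,
parameter semantics and design choices.

## Worked example

The packaged top-30 fold-change fixture exercises the SI statistic on
published replicate-mean FC triples:

```r
library(sicobind)
fx <- si_fixture_check("alpha")   # IFNα + LPS table
fx$n_flagged
#> [1] 25
fx$table$gene_id[!fx$table$si_flag]
#> [1] "Ifi44"   "Gm15725" "Apod"    "Gm14446" "Tgtp2"
head(fx$table[, c("gene_id", "fc_ifn", "fc_lps", "fc_combo", "si_flag")], 5)
#>         gene_id fc_ifn fc_lps fc_combo si_flag
#> 1 F830016B08Rik  196.8    6.4    345.9    TRUE
#> 2         Ifi44  356.3    4.4    343.7   FALSE
#> 3        Cxcl10   75.9    4.6    312.1    TRUE
#> 4      BC023105  187.1   19.9    289.2    TRUE
#> 5          Nos2    4.9   90.9    287.1    TRUE
```

25 of 30 genes are SI-flagged: e.g. Nos2 (287.1 > 4.9 + 90.9) is
super-additive, while Ifi44 (343.7 < 356.3 + 4.4) responds to IFNα alone
with no synergy.

A full simulated run — generate a toy study, analyze it, and score
recovery against the planted truth:

```r
res <- run_pipeline(list(
  simulate = list(n_chroms = 2, chrom_length = 1500000, n_genes = 60, seed = 1),
  outdir = tempfile()))
str(res$summary$recovery)
#> List of 4
#>  $ mode_accuracy_pct : num 100
#>  $ si_sensitivity_pct: num 100
#>  $ si_specificity_pct: num 98.2
#>  $ n_motif_genes     : int 14
unlist(res$summary$mode_counts$IFNg_LPS)
#>           GAS      GAS-ISRE GAS-ISRE-NFKB      GAS-NFKB          ISRE
#>             2             2             2             2             2
#>     ISRE-NFKB          NFKB
#>             2             2
```

Every planted binding mode is recovered for all 14 motif-bearing genes;
SI specificity is 98.2% (one borderline non-SI gene flipped by replicate
noise — the margin for single-arm responders is inherently a few percent
of the FC). The output directory holds the TSV catalogs (expression
records, SI records, Venn counts, promoter sites, occupied sites, modes,
overlaps, summit histograms, occupancy clusters) and `summary.json`.

A thin CLI over the same functions is installed at
`inst/scripts/sicobind-pipeline.R` (subcommands `simulate`, `run`,
`report`, YAML config as in `?pipeline_config`).

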