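iv <- function(start, end, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

test_that("interval algebra follows half-open semantics", {
  expect_equal(interval_ops(iv(0L, 100L), iv(40L, 60L), "subtract"),
               iv(c(0L, 60L), c(40L, 100L)))
  expect_identical(nrow(interval_ops(iv(0L, 10L), iv(20L, 30L), "intersect")), 0L)
  expect_equal(interval_ops(iv(0L, 10L), iv(10L, 20L), "merge"), iv(0L, 20L))
  # chromosomes are independent
  got <- interval_ops(iv(0L, 50L), iv(10L, 20L, chrom = "chr2"), "subtract")
  expect_equal(got, iv(0L, 50L))
  expect_error(interval_ops(iv(5L, 5L), iv(0L, 1L), "intersect"), "malformed")
})

test_that("interval algebra equals the per-base membership oracle", {
  set.seed(40)
  for (i in 1:30) {
    a <- random_intervals(sample(1:8, 1))
    b <- random_intervals(sample(1:8, 1))
    for (op in c("intersect", "subtract", "merge")) {
      got <- interval_ops(a, b, op)
      want <- oracle_interval_op(a, b, op)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("occupancy requires full containment in a matching factor's peak", {
  hits <- data.frame(pwm_id = "m", motif_class = c("GAS", "GAS", "GAS", "NFKB"),
                     chrom = "chr1",
                     start = c(150L, 150L, 280L, 150L),
                     end = c(160L, 160L, 310L, 160L),
                     strand = "+", log_odds = 8, stringsAsFactors = FALSE)
  hits <- hits[c(1, 3, 4), ]
  peaks <- rbind(make_peak("chr1", 100L, 300L, "STAT1", "IFNa_LPS"),
                 make_peak("chr1", 100L, 300L, "p65", "IFNa_LPS"),
                 make_peak("chr1", 140L, 170L, "STAT1", "IFNg_LPS"))
  occ <- occupied_sites(hits, peaks, "IFNa_LPS")
  # GAS inside STAT1 peak: occupied; GAS straddling the edge: not;
  # NFKB hit inside the p65 peak: occupied through its own factor
  expect_identical(occ$motif_class, c("GAS", "NFKB"))
  expect_identical(occ$start, c(150L, 150L))
  expect_identical(occ$peak_start, c(100L, 100L))

  # a GAS hit covered only by p65 peaks is never occupied
  occ2 <- occupied_sites(hits[1L, ],
                         make_peak("chr1", 100L, 300L, "p65", "IFNa_LPS"),
                         "IFNa_LPS")
  expect_identical(nrow(occ2), 0L)
  # condition mismatch does not occupy either
  occ3 <- occupied_sites(hits[1L, ], peaks, "LPS")
  expect_identical(nrow(occ3), 0L)
})

test_that("nearest-TSS annotation signs, filters and tie-breaks distances", {
  genes <- rbind(make_gene("alpha", "chr1", 10000L, 12000L, "+"),
                 make_gene("beta", "chr1", 10600L, 13000L, "+"))
  site_at <- function(mid) iv(mid - 5L, mid + 5L)
  ann <- annotate_nearest_tss(site_at(10000L), genes)
  expect_identical(ann$gene_id, "alpha")
  expect_identical(ann$tss_distance, 0L)

  # two TSSs at -300/+300: lexicographic tie-break
  ann2 <- annotate_nearest_tss(site_at(10300L), genes)
  expect_identical(ann2$gene_id, "alpha")
  expect_identical(ann2$tss_distance, 300L)

  # beyond the 100 kb window: none
  far <- annotate_nearest_tss(site_at(500000L), genes)
  expect_true(is.na(far$gene_id))

  # minus-strand sign flip: site downstream of transcription is positive
  gm <- make_gene("gm", "chr1", 10000L, 12000L, "-")   # tss 11999
  annm <- annotate_nearest_tss(site_at(11000L), gm)
  expect_identical(annm$tss_distance, 999L)
})

test_that("genomic categories follow the documented precedence", {
  g <- make_gene("g", "chr1", 10000L, 20000L, "+",
                 cds_start = 11500L, cds_end = 18500L,
                 exons = cbind(start = c(10000L, 15000L, 18000L),
                               end = c(12000L, 16000L, 20000L)))
  cat_at <- function(mid) genomic_category(
    data.frame(chrom = "chr1", start = mid - 5L, end = mid + 5L,
               gene_id = "g", stringsAsFactors = FALSE), g)
  expect_identical(cat_at(9500L), "promoter/TSS")    # TSS - 500
  expect_identical(cat_at(10050L), "promoter/TSS")   # +50 inside gene
  expect_identical(cat_at(11000L), "5'UTR")          # exonic, before CDS
  expect_identical(cat_at(15500L), "exon")           # coding exon
  expect_identical(cat_at(14000L), "intron")
  expect_identical(cat_at(19000L), "3'UTR")          # exonic, after CDS
  expect_identical(cat_at(19950L), "TTS")            # within 100 bp of TTS
  expect_identical(genomic_category(
    data.frame(chrom = "chr1", start = 69995L, end = 70005L,
               gene_id = NA_character_), g), "intergenic")

  # strand awareness: promoter of a minus-strand gene sits above its end
  gm <- make_gene("gm", "chr1", 10000L, 20000L, "-")
  cat_m <- genomic_category(
    data.frame(chrom = "chr1", start = 20495L, end = 20505L,
               gene_id = "gm", stringsAsFactors = FALSE), gm)
  expect_identical(cat_m, "promoter/TSS")

  # categories partition: exactly one label per site, always defined
  set.seed(41)
  mids <- sample.int(30000L, 100L) + 5000L
  cats <- genomic_category(
    data.frame(chrom = "chr1", start = mids - 5L, end = mids + 5L,
               gene_id = "g", stringsAsFactors = FALSE), g)
  expect_true(all(cats %in% sicobind:::GENOMIC_CATEGORIES))
  expect_length(cats, 100L)
})

test_that("binding modes are the occupied class set in canonical order", {
  mk <- function(classes) {
    data.frame(pwm_id = "m", motif_class = classes, chrom = "chr1",
               start = seq(1000L, by = 100L, length.out = length(classes)),
               end = seq(1010L, by = 100L, length.out = length(classes)),
               strand = "+", log_odds = 8, gene_id = "g",
               tss_distance = 0L, stringsAsFactors = FALSE)
  }
  expect_identical(classify_binding_mode(mk(c("NFKB", "ISRE", "GAS")),
                                         "IFNa_LPS")$mode, "GAS-ISRE-NFKB")
  expect_identical(classify_binding_mode(mk("ISRE"), "IFNa_LPS")$mode, "ISRE")
  expect_identical(classify_binding_mode(mk("NFKB"), "IFNa_LPS")$mode, "NFKB")
  # min spacing between sites of different classes
  rec <- classify_binding_mode(mk(c("GAS", "NFKB")), "IFNg_LPS")
  expect_identical(rec$min_spacing, 100L)
  expect_identical(rec$n_sites, 2L)
  # genes with no occupied sites yield no record
  empty <- classify_binding_mode(mk("GAS")[0, ], "IFNa_LPS")
  expect_identical(nrow(empty), 0L)
})

test_that("mode overlap percentages use both denominators correctly", {
  ma <- data.frame(gene_id = paste0("g", 1:10), mode = "NFKB")
  ident <- mode_overlap_table(ma, ma)
  row <- ident[ident$mode == "NFKB", ]
  expect_equal(row$pct_sum, 50)
  expect_equal(row$pct_jaccard, 100)
  expect_equal(ident$pct_sum[ident$mode == "GAS"], 0)

  # back-solved fixture: |A| 85, |B| 28, |A n B| 18 -> 15.93 by sum
  a <- data.frame(gene_id = paste0("x", 1:85), mode = "NFKB")
  b <- data.frame(gene_id = c(paste0("x", 1:18), paste0("y", 1:10)),
                  mode = "NFKB")
  got <- mode_overlap_table(a, b)
  expect_equal(round(got$pct_sum[got$mode == "NFKB"], 2), 15.93)

  disj <- mode_overlap_table(
    a, data.frame(gene_id = paste0("z", 1:5), mode = "NFKB"))
  expect_equal(disj$pct_sum[disj$mode == "NFKB"], 0)
})

test_that("summit distances match a quadratic all-pairs oracle", {
  s0 <- make_peak("chr1", 1000L, 1200L, "STAT1", "IFNa_LPS",
                  summit_offset = 100L)
  p0 <- make_peak("chr1", 1000L, 1200L, "p65", "IFNa_LPS",
                  summit_offset = 100L)
  res <- summit_distance_histogram(s0, p0)
  expect_identical(res$distances, 0L)
  center_bin <- res$histogram[res$histogram$bin_start == 0, ]
  expect_identical(center_bin$count, 1L)

  set.seed(42)
  s1 <- make_peak("chr1", s <- sort(sample.int(50000L, 60)), s + 200L,
                  "STAT1", "IFNg_LPS", summit_offset = sample.int(199L, 60))
  p6 <- make_peak("chr1", q <- sort(sample.int(50000L, 40)), q + 200L,
                  "p65", "IFNg_LPS", summit_offset = sample.int(199L, 40))
  res2 <- summit_distance_histogram(s1, p6)
  ssum <- s1$start + s1$summit_offset
  psum <- p6$start + p6$summit_offset
  want <- vapply(ssum, function(x) {
    d <- psum - x
    d[[which.min(abs(d))]]
  }, 0L)
  expect_identical(res2$distances, want)
  # out-of-range distances live in the list, not the histogram
  expect_identical(sum(res2$histogram$count),
                   sum(want >= -1000L & want < 1000L))
  expect_error(summit_distance_histogram(s1, p6, bin = 33L), "divide")
})

test_that("RPKM is reads per kilobase per million and respects zeros", {
  region <- iv(0L, 1000L)
  cov_main <- data.frame(chrom = "chr1", start = seq(0L, 975L, by = 25L),
                         end = seq(25L, 1000L, by = 25L), value = 0.25)
  filler <- data.frame(chrom = "chr1", start = 2000L, end = 2025L,
                       value = 1e6 - 10)
  coverage <- list(s1 = rbind(cov_main, filler),
                   s2 = data.frame(chrom = "chr1", start = 0L, end = 25L,
                                   value = 0))
  suppressWarnings(
    res <- rpkm_and_cluster(rbind(region, iv(2000L, 3000L)), coverage,
                            k = 1L, seed = 1L))
  # 10 reads in a 1 kb region out of 1e6 total -> RPKM 10
  expect_equal(unname(res$rpkm[1L, "s1"]), 10)
  expect_equal(unname(res$rpkm[, "s2"]), c(0, 0))
  expect_error(rpkm_and_cluster(region, coverage, k = 5L), "exceeds")
})

test_that("k-means separates planted occupancy archetypes", {
  skip_if_not_installed("mclust")
  sim <- simulate_study(small_sim_config(seed = 43L))
  truth <- sim$truth
  # STAT1-only archetype: GAS/ISRE motifs of STAT-only genes;
  # co-bound archetype: NFKB motifs of composite genes
  stat_only <- truth$genes$gene_id[truth$genes$mode %in% c("GAS", "ISRE", "GAS-ISRE")]
  cobound <- truth$genes$gene_id[truth$genes$mode %in%
                                   c("GAS-NFKB", "ISRE-NFKB", "GAS-ISRE-NFKB")]
  m <- truth$motifs
  pick <- rbind(
    cbind(m[m$gene_id %in% stat_only & m$motif_class != "NFKB", ], label = 1L),
    cbind(m[m$gene_id %in% cobound & m$motif_class == "NFKB", ], label = 2L))
  regions <- data.frame(chrom = pick$chrom,
                        start = pick$start - 100L, end = pick$end + 100L)
  res <- rpkm_and_cluster(regions, sim$coverage, k = 2L, seed = 5L)
  ari <- mclust::adjustedRandIndex(res$cluster, pick$label)
  expect_gte(ari, 0.9)
})
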