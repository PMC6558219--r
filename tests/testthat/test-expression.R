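make_cm <- function(mat, conditions, cell_type = "VSMC") {
  n <- ncol(mat)
  smp <- data.frame(sample = paste0("s", seq_len(n)), cell_type = cell_type,
                    condition = conditions,
                    replicate = stats::ave(seq_len(n), conditions,
                                           FUN = seq_along))
  colnames(mat) <- smp$sample
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  count_matrix(mat, smp)
}

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(5L, 7L, 11L), 3, 4, dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(unname(size_factors(m)), rep(1, 4))

  # hand oracle: ratios to the geometric mean are constant per column
  m2 <- matrix(c(10L, 100L, 4L, 20L, 200L, 8L), 3, 2)
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))

  # doubling one column of an all-positive matrix doubles its factor
  set.seed(3)
  m3 <- matrix(rpois(60, 50) + 1L, 10, 6)
  f3 <- size_factors(m3)
  m3b <- m3; m3b[, 2L] <- m3b[, 2L] * 2L
  expect_equal(size_factors(m3b)[2L] / f3[2L] /
                 (size_factors(m3b)[1L] / f3[1L]), 2,
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2, 2)),
               "no gene has positive counts")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  # odd gene count: both implementations select the same median element
  # (with an even count DESeq2 interpolates in log space, ours on ratios)
  set.seed(4)
  m <- matrix(rnbinom(606, mu = 80, size = 10) + 1L, 101, 6,
              dimnames = list(paste0("g", 1:101), paste0("s", 1:6)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("the expressed filter is a strict cutoff on replicate means", {
  # gene means per condition: g1 control 8 treated 8; g2 treated 8.01-ish
  mat <- matrix(c(8L, 8L, 8L, 8L,
                  0L, 0L, 9L, 7L,     # mean 8 in LPS
                  0L, 0L, 9L, 8L),    # mean 8.5 in LPS
                3, 4, byrow = TRUE)
  cm <- make_cm(mat, c("control", "control", "LPS", "LPS"))
  nf <- normalize_and_filter(cm, factors = rep(1, 4), cutoff = 8)
  expect_false("g1" %in% nf$expressed$VSMC)   # 8.0 excluded: strict >
  expect_false("g2" %in% nf$expressed$VSMC)
  expect_true("g3" %in% nf$expressed$VSMC)    # 8.5 in one condition suffices
  nf0 <- normalize_and_filter(cm, factors = rep(1, 4), cutoff = 0)
  expect_setequal(nf0$expressed$VSMC, c("g1", "g2", "g3"))
})

test_that("fold changes use the symmetric pseudocount and flag boundaries", {
  mat <- matrix(c(10L, 10L, 40L, 40L,    # FC (40+.5)/(10+.5)
                  10L, 10L, 10L, 10L,    # identity
                  0L,  0L,  10L, 10L,    # induced from zero
                  10L, 10L, 20L, 20L),   # boundary FC 2 (with eps: 20.5/10.5)
                4, 4, byrow = TRUE)
  cm <- make_cm(mat, c("control", "control", "LPS", "LPS"))
  nf <- normalize_and_filter(cm, factors = rep(1, 4), cutoff = 0)
  rec <- fold_changes(nf, epsilon = 0.5)
  fc <- setNames(rec$fc, rec$gene_id)
  expect_equal(fc[["g1"]], 40.5 / 10.5)
  expect_equal(fc[["g2"]], 1)
  expect_equal(fc[["g3"]], 21)
  # boundary: FC exactly 2 is up under the default >= rule, not under strict
  nf2 <- normalize_and_filter(cm, factors = rep(1, 4), cutoff = 0)
  rec0 <- fold_changes(nf2, epsilon = 0)
  expect_equal(rec0$fc[rec0$gene_id == "g4"], 2)
  expect_true(rec0$up[rec0$gene_id == "g4"])
  rec_strict <- fold_changes(nf2, epsilon = 0, strict_cutoff = TRUE)
  expect_false(rec_strict$up[rec_strict$gene_id == "g4"])

  expect_error(fold_changes(nf, required = "IFNa"), "missing condition IFNa")
})

test_that("up lists are FC-sorted and invariant to global count rescaling", {
  set.seed(5)
  base <- matrix(rpois(200, 60) + 1L, 50, 4)
  base[1:10, 3:4] <- base[1:10, 3:4] * 9L
  cm <- make_cm(base, c("control", "control", "LPS", "LPS"))
  up1 <- up_regulated_lists(fold_changes(normalize_and_filter(cm)))
  cm2 <- make_cm(base * 3L, c("control", "control", "LPS", "LPS"))
  up2 <- up_regulated_lists(fold_changes(normalize_and_filter(cm2)))
  expect_identical(up1, up2)
  r <- fold_changes(normalize_and_filter(cm))
  fcs <- setNames(r$fc, r$gene_id)[up1$VSMC$LPS]
  expect_false(is.unsorted(rev(fcs)))
})

test_that("three-set Venn partitions the union exactly", {
  idlists <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("c", "e"))
  cg <- common_genes(idlists)
  expect_identical(cg$common, "c")
  expect_identical(sum(cg$venn), 5L)   # |union|
  expect_identical(unname(cg$venn[["A-B-C"]]), 1L)

  same <- list(X = letters[1:4], Y = letters[1:4], Z = letters[1:4])
  cs <- common_genes(same)
  expect_setequal(cs$common, letters[1:4])
  expect_identical(unname(cs$venn[["X-Y-Z"]]), 4L)
  expect_identical(sum(cs$venn[1:6]), 0L)

  disj <- list(X = "a", Y = "b", Z = "c")
  expect_length(common_genes(disj)$common, 0L)

  # property: counts always sum to the union size
  set.seed(6)
  for (i in 1:20) {
    l <- replicate(3, sample(letters, sample(0:15, 1)), simplify = FALSE)
    expect_identical(sum(venn_counts3(l[[1]], l[[2]], l[[3]])),
                     length(unique(unlist(l))))
  }
})

test_that("SI flags are the strict super-additivity rule", {
  tab <- data.frame(gene_id = c("Nos2", "Ifi44", "Apod"),
                    fc_ifn = c(4.9, 356.3, 213.7),
                    fc_lps = c(90.9, 4.4, 2.2),
                    fc_combo = c(287.1, 343.7, 194.9))
  out <- si_flags(tab)
  expect_identical(out$si_flag, c(TRUE, FALSE, FALSE))
})

test_that("SI flags derived from records match direct triple evaluation", {
  set.seed(7)
  mu <- matrix(rpois(30 * 6, 40) + 1L, 30, 6)
  mat <- cbind(mu, mu[, 1:3] * 2L, mu[, 1:3] * 5L)[, c(1:6, 7:12)]
  cm <- make_cm(mat,
                rep(c("control", "IFNa", "LPS", "IFNa_LPS"), each = 3))
  rec <- fold_changes(normalize_and_filter(cm, factors = rep(1, 12), cutoff = 0))
  si <- si_flags(rec)
  r <- rec[rec$cell_type == "VSMC", ]
  for (i in seq_len(nrow(si))) {
    g <- si$gene_id[[i]]
    expect_identical(si$si_flag[[i]],
                     si$fc_combo[[i]] > si$fc_ifn[[i]] + si$fc_lps[[i]])
    expect_equal(si$fc_combo[[i]], r$fc[r$gene_id == g & r$condition == "IFNa_LPS"])
  }
})

test_that("pairwise overlap reproduces both denominator conventions", {
  A <- paste0("a", 1:579); B <- c(A[1:436], paste0("b", 1:100))
  expect_equal(round(pairwise_overlap(A, B, "jaccard"), 2), 64.21)
  A2 <- paste0("x", 1:81); B2 <- c(A2[1:37], paste0("y", 1:8))
  expect_equal(round(pairwise_overlap(A2, B2, "sum"), 1), 29.4)
  expect_identical(pairwise_overlap("a", "b", "jaccard"), 0)
  expect_identical(pairwise_overlap(character(), character(), "sum"), 0)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  universe <- paste0("g", 1:10)
  gene_set <- universe[1:5]
  res <- enrich_gene_sets(universe[1:5], universe, list(s = gene_set))
  expect_equal(res$p, 1 / choose(10, 5))
  expect_true(res$significant)

  # enumeration oracle: all 5-subsets of the universe
  combos <- utils::combn(10, 5)
  k_obs <- 4
  p_enum <- mean(apply(combos, 2, function(ix)
    sum(ix <= 5) >= k_obs))
  res2 <- enrich_gene_sets(c(universe[1:4], "g10"), universe, list(s = gene_set))
  expect_equal(res2$p, p_enum)

  res3 <- enrich_gene_sets(universe[6:10], universe, list(s = universe))
  expect_equal(res3$overlap, 5L)
  expect_equal(res3$p, 1)

  expect_error(enrich_gene_sets("g1", character(), list(s = "g1")), "empty")
})

test_that("expression summaries use interpolated quartiles", {
  # per-gene IFNa FCs: 2, 4, 8, 16 -> log2 FCs 1, 2, 3, 4; LPS constant FC 4
  mat <- matrix(c(10L, 10L, 20L, 20L, 40L, 40L,
                  10L, 10L, 40L, 40L, 40L, 40L,
                  10L, 10L, 80L, 80L, 40L, 40L,
                  10L, 10L, 160L, 160L, 40L, 40L), 4, 6, byrow = TRUE)
  cm <- make_cm(mat, rep(c("control", "IFNa", "LPS"), each = 2))
  rec <- fold_changes(normalize_and_filter(cm, factors = rep(1, 6), cutoff = 0),
                      epsilon = 0)
  sm <- expression_summary(rec, paste0("g", 1:4))
  expect_equal(unname(sm$log2fc[, "IFNa"]), 1:4, ignore_attr = TRUE)
  # quartile convention: median of {1,2,3,4} by linear interpolation is 2.5
  expect_equal(sm$summary$median[sm$summary$condition == "IFNa"], 2.5)
  expect_equal(sm$summary$q1[sm$summary$condition == "IFNa"], 1.75)
  # constant log2 FC list: median equals the value, IQR 0
  expect_equal(sm$summary$median[sm$summary$condition == "LPS"], 2)
  expect_equal(sm$summary$q3[sm$summary$condition == "LPS"] -
                 sm$summary$q1[sm$summary$condition == "LPS"], 0)
})
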