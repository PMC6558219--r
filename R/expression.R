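# Replicate-count normalization, fold changes, cross-cell-type commonality,
# signal-integration (SI) flagging and gene-set enrichment.

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over genes with
#' all-positive counts of `count[i, j] / geometric_mean_i`, the DESeq
#' median-of-ratios estimator.
#'
#' @param x A `count_matrix` or a non-negative numeric matrix.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(x) {
  mat <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  keep <- rowSums(mat > 0) == ncol(mat)
  if (!any(keep))
    stop("no gene has positive counts in every sample; ",
         "the pseudo-reference fallback is deliberately not applied",
         call. = FALSE)
  lg <- log(mat[keep, , drop = FALSE])
  ref <- rowMeans(lg)                       # log geometric mean per gene
  f <- apply(exp(lg - ref), 2L, stats::median)
  names(f) <- colnames(mat)
  f
}

#' Normalize counts and apply the expressed-gene filter
#'
#' Normalized signal is `count / size_factor`. A gene counts as expressed
#' in a cell type iff its replicate-mean normalized signal exceeds
#' `cutoff` (strictly) in at least one condition of that cell type.
#'
#' @param x A `count_matrix`.
#' @param factors Per-sample size factors from [size_factors()].
#' @param cutoff Lower cutoff on the normalized replicate-mean signal.
#' @return list(normalized = matrix, condition_means = per cell type a
#'   genes x condition matrix, expressed = per cell type a character vector
#'   of expressed gene ids).
#' @export
normalize_and_filter <- function(x, factors = size_factors(x), cutoff = 8) {
  norm <- sweep(x$counts, 2L, factors, "/")
  smp <- x$samples
  condition_means <- list()
  expressed <- list()
  for (ct in unique(smp$cell_type)) {
    conds <- unique(smp$condition[smp$cell_type == ct])
    m <- sapply(conds, function(cd) {
      cols <- smp$sample[smp$cell_type == ct & smp$condition == cd]
      rowMeans(norm[, cols, drop = FALSE])
    })
    m <- matrix(m, nrow = nrow(norm), dimnames = list(rownames(norm), conds))
    condition_means[[ct]] <- m
    expressed[[ct]] <- rownames(norm)[apply(m, 1L, max) > cutoff]
  }
  list(normalized = norm, condition_means = condition_means,
       expressed = expressed)
}

#' Per-condition fold changes versus control
#'
#' FC = (mean(treated) + epsilon) / (mean(control) + epsilon) on the
#' normalized replicate-mean scale. The symmetric pseudocount keeps FCs
#' finite for induced-from-zero genes without reordering them.
#'
#' @param norm Result of [normalize_and_filter()].
#' @param fc_cutoff Fold-change threshold for the up flag.
#' @param strict_cutoff If `FALSE` (default) the boundary FC is
#'   up-regulated (`FC >= cutoff`); if `TRUE`, strictly greater.
#' @param epsilon Pseudocount added to both condition means.
#' @param required Conditions that must be present for every cell type
#'   (besides control); a missing one is an error naming it.
#' @return data.frame of expression records: gene_id, cell_type, condition,
#'   mean_treated, mean_control, fc, log2fc, expressed, up.
#' @export
fold_changes <- function(norm, fc_cutoff = 2, strict_cutoff = FALSE,
                         epsilon = 0.5, required = NULL) {
  recs <- list()
  for (ct in names(norm$condition_means)) {
    m <- norm$condition_means[[ct]]
    if (!"control" %in% colnames(m)) stopf("cell type %s: missing condition control", ct)
    missing <- setdiff(required, colnames(m))
    if (length(missing))
      stopf("cell type %s: missing condition %s", ct, missing[[1L]])
    ctrl <- m[, "control"]
    for (cd in setdiff(colnames(m), "control")) {
      fc <- (m[, cd] + epsilon) / (ctrl + epsilon)
      up_fc <- if (strict_cutoff) fc > fc_cutoff else fc >= fc_cutoff
      recs[[paste(ct, cd)]] <- data.frame(
        gene_id = rownames(m), cell_type = ct, condition = cd,
        mean_treated = m[, cd], mean_control = ctrl,
        fc = fc, log2fc = log2(fc),
        expressed = rownames(m) %in% norm$expressed[[ct]],
        up = up_fc & rownames(m) %in% norm$expressed[[ct]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Up-regulated gene lists per (cell type, condition)
#'
#' @param records Expression records from [fold_changes()].
#' @return Nested list `lists[[cell_type]][[condition]]` of gene ids
#'   sorted by descending fold change.
#' @export
up_regulated_lists <- function(records) {
  out <- list()
  for (ct in unique(records$cell_type)) {
    out[[ct]] <- list()
    for (cd in unique(records$condition[records$cell_type == ct])) {
      r <- records[records$cell_type == ct & records$condition == cd &
                     records$up, , drop = FALSE]
      out[[ct]][[cd]] <- r$gene_id[order(-r$fc)]
    }
  }
  out
}

#' Three-set Venn partition counts
#'
#' @param a,b,c Character vectors (membership lists).
#' @param labels Labels for the three sets.
#' @return Named integer vector over the 7 regions
#'   (`A`, `B`, `C`, `A-B`, `A-C`, `B-C`, `A-B-C` with the given labels);
#'   exclusive regions first. Counts partition the union exactly.
#' @export
venn_counts3 <- function(a, b, c, labels = c("A", "B", "C")) {
  u <- unique(c(a, b, c))
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  n <- c(sum(ina & !inb & !inc), sum(!ina & inb & !inc), sum(!ina & !inb & inc),
         sum(ina & inb & !inc), sum(ina & !inb & inc), sum(!ina & inb & inc),
         sum(ina & inb & inc))
  names(n) <- c(labels,
                paste(labels[[1L]], labels[[2L]], sep = "-"),
                paste(labels[[1L]], labels[[3L]], sep = "-"),
                paste(labels[[2L]], labels[[3L]], sep = "-"),
                paste(labels, collapse = "-"))
  n
}

#' Genes common to three per-cell-type up lists
#'
#' @param lists List of three character vectors (one per cell type).
#' @param labels Set labels for the Venn region names.
#' @return list(common = triple intersection, venn = 7-region counts).
#' @export
common_genes <- function(lists, labels = names(lists)) {
  if (length(lists) != 3L) stopf("common_genes expects exactly three lists")
  if (is.null(labels)) labels <- c("A", "B", "C")
  common <- Reduce(intersect, lists)
  list(common = common,
       venn = venn_counts3(lists[[1L]], lists[[2L]], lists[[3L]], labels = labels))
}

#' Signal-integration (super-additivity) flags
#'
#' A gene is SI-flagged for a combined condition iff the combined-treatment
#' fold change strictly exceeds the sum of the single-treatment fold
#' changes: `fc_combo > fc_ifn + fc_lps`.
#'
#' @param records Expression records from [fold_changes()], or a
#'   data.frame with columns gene_id, fc_ifn, fc_lps, fc_combo (and
#'   optionally cell_type, combo).
#' @return data.frame of SI records: gene_id, cell_type, combo, fc_ifn,
#'   fc_lps, fc_combo, si_flag.
#' @export
si_flags <- function(records) {
  if (all(c("fc_ifn", "fc_lps", "fc_combo") %in% names(records))) {
    out <- records
    if (is.null(out$cell_type)) out$cell_type <- "VSMC"
    if (is.null(out$combo)) out$combo <- NA_character_
    out$si_flag <- out$fc_combo > out$fc_ifn + out$fc_lps
    return(out[, c("gene_id", "cell_type", "combo", "fc_ifn", "fc_lps",
                   "fc_combo", "si_flag")])
  }
  combos <- list(IFNa_LPS = "IFNa", IFNg_LPS = "IFNg")
  res <- list()
  for (ct in unique(records$cell_type)) {
    r <- records[records$cell_type == ct, , drop = FALSE]
    fc_of <- function(cd) {
      v <- r$fc[r$condition == cd]
      names(v) <- r$gene_id[r$condition == cd]
      v
    }
    if (!any(r$condition %in% names(combos))) next
    if (!"LPS" %in% r$condition)
      stopf("cell type %s: missing condition LPS", ct)
    lps <- fc_of("LPS")
    for (combo in names(combos)) {
      if (!combo %in% r$condition) next
      if (!combos[[combo]] %in% r$condition)
        stopf("cell type %s: missing condition %s", ct, combos[[combo]])
      ifn <- fc_of(combos[[combo]])
      cmb <- fc_of(combo)
      g <- names(cmb)
      res[[paste(ct, combo)]] <- data.frame(
        gene_id = g, cell_type = ct, combo = combo,
        fc_ifn = ifn[g], fc_lps = lps[g], fc_combo = cmb[g],
        si_flag = cmb[g] > ifn[g] + lps[g],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Percentage overlap of two gene lists
#'
#' `jaccard` = 100 * |A n B| / |A u B|; `sum` = 100 * |A n B| /
#' (|A| + |B|). Both conventions are provided because printed overlap
#' percentages in this analysis family back-solve to different
#' denominators in different figures.
#'
#' @param a,b Character vectors.
#' @param method `"jaccard"` or `"sum"`.
#' @return Percentage (0 if both lists are empty).
#' @export
pairwise_overlap <- function(a, b, method = c("jaccard", "sum")) {
  method <- match.arg(method)
  a <- unique(a); b <- unique(b)
  i <- length(intersect(a, b))
  denom <- switch(method, jaccard = length(union(a, b)),
                  sum = length(a) + length(b))
  if (denom == 0L) return(0)
  100 * i / denom
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric p-value of the overlap between a gene list
#' and each set, given the universe. Sets with p < `alpha` are flagged.
#'
#' @param genes Gene list (must be a subset of `universe`).
#' @param universe Background gene ids.
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param alpha Significance cutoff.
#' @return data.frame: set, set_size (within universe), overlap, p,
#'   significant; sorted by p.
#' @export
enrich_gene_sets <- function(genes, universe, gene_sets, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0L) stopf("empty gene universe")
  genes <- unique(genes)
  if (!all(genes %in% universe)) stopf("gene list is not a subset of the universe")
  N <- length(universe); n <- length(genes)
  rows <- lapply(names(gene_sets), function(nm) {
    K <- length(intersect(gene_sets[[nm]], universe))
    k <- length(intersect(gene_sets[[nm]], genes))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' log2 fold-change matrix and per-condition summary for a gene subset
#'
#' @param records Expression records from [fold_changes()].
#' @param genes Gene subset (ids present in `records`).
#' @param cell_type Cell type to summarize.
#' @return list(log2fc = genes x condition matrix, summary = data.frame
#'   condition, median, q1, q3 with quartiles by linear interpolation).
#' @export
expression_summary <- function(records, genes, cell_type = "VSMC") {
  r <- records[records$cell_type == cell_type & records$gene_id %in% genes, ]
  if (!all(genes %in% r$gene_id)) stopf("gene subset not contained in records")
  conds <- unique(r$condition)
  m <- sapply(conds, function(cd) {
    v <- r$log2fc[r$condition == cd]
    names(v) <- r$gene_id[r$condition == cd]
    v[genes]
  })
  m <- matrix(m, nrow = length(genes), dimnames = list(genes, conds))
  qs <- t(apply(m, 2L, stats::quantile, probs = c(0.25, 0.5, 0.75),
                type = 7, names = FALSE))
  list(log2fc = m,
       summary = data.frame(condition = conds, median = qs[, 2L],
                            q1 = qs[, 1L], q3 = qs[, 3L],
                            stringsAsFactors = FALSE))
}
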