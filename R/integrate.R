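# Interval algebra, motif-in-peak occupancy, nearest-TSS annotation,
# genomic-location classification, binding-mode calls, summit-distance
# histograms and RPKM occupancy clustering.

to_iranges <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)

from_iranges <- function(ir, chrom) {
  data.frame(chrom = rep(chrom, length(ir)),
             start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
             stringsAsFactors = FALSE)
}

check_intervals <- function(df, what) {
  if (nrow(df) && any(df$start >= df$end | df$start < 0))
    stopf("malformed interval in %s", what)
}

#' Intersect, subtract or merge two interval sets
#'
#' Half-open 0-based semantics throughout; chromosomes are handled
#' independently. `merge` coalesces touching intervals of the union
#' (`[0,10) + [10,20) -> [0,20)`).
#'
#' @param a,b data.frames with chrom, start, end (for `merge`, `b` may be
#'   `NULL` to merge `a` alone).
#' @param op One of `"intersect"`, `"subtract"`, `"merge"`.
#' @return data.frame chrom, start, end, sorted by (chrom, start).
#' @export
interval_ops <- function(a, b = NULL, op = c("intersect", "subtract", "merge")) {
  op <- match.arg(op)
  if (is.null(b)) b <- a[0, , drop = FALSE]
  check_intervals(a, "set A"); check_intervals(b, "set B")
  chroms <- sort(unique(c(a$chrom, b$chrom)))
  out <- lapply(chroms, function(ch) {
    ia <- to_iranges(a[a$chrom == ch, , drop = FALSE])
    ib <- to_iranges(b[b$chrom == ch, , drop = FALSE])
    ir <- switch(op,
                 intersect = IRanges::intersect(ia, ib),
                 subtract = IRanges::setdiff(ia, ib),
                 merge = IRanges::reduce(c(ia, ib)))
    from_iranges(ir, ch)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Motif hits occupied by a matching factor's peaks
#'
#' A GAS or ISRE hit is occupied iff it lies fully inside a STAT1 peak of
#' the given condition; an NFKB hit iff fully inside a p65 peak. A factor
#' mismatch never occupies, and partial overlap does not count.
#'
#' @param hits Motif-hit data.frame (from the scanners).
#' @param peaks Peak data.frame (possibly several factors/conditions).
#' @param condition Condition whose peaks are used.
#' @return The occupied subset of `hits` with peak_start, peak_end,
#'   peak_summit (absolute coordinate) columns added.
#' @export
occupied_sites <- function(hits, peaks, condition) {
  class_factor <- c(GAS = "STAT1", ISRE = "STAT1", NFKB = "p65")
  keep <- integer(0)
  pk_idx <- integer(0)
  pk <- peaks[peaks$condition == condition, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    fac <- class_factor[[hits$motif_class[[i]]]]
    j <- which(pk$factor == fac & pk$chrom == hits$chrom[[i]] &
                 pk$start <= hits$start[[i]] & pk$end >= hits$end[[i]])
    if (length(j)) {
      keep <- c(keep, i)
      pk_idx <- c(pk_idx, j[[1L]])
    }
  }
  out <- hits[keep, , drop = FALSE]
  out$peak_start <- pk$start[pk_idx]
  out$peak_end <- pk$end[pk_idx]
  out$peak_summit <- pk$start[pk_idx] + pk$summit_offset[pk_idx]
  rownames(out) <- NULL
  out
}

site_midpoint <- function(sites) (sites$start + sites$end) %/% 2L

#' Annotate sites to the nearest TSS within a distance window
#'
#' Distance is `site midpoint - TSS`, with the sign flipped on `-` strand
#' genes so that positive means downstream of transcription. The nearest
#' gene by absolute distance is chosen (ties broken lexicographically by
#' gene id); sites farther than `tss_window` from every TSS get `NA`.
#'
#' @param sites data.frame with chrom, start, end.
#' @param genes Gene-model data.frame.
#' @param tss_window Maximum absolute distance in bp.
#' @return `sites` with gene_id and tss_distance columns added (`NA` when
#'   no gene qualifies).
#' @export
annotate_nearest_tss <- function(sites, genes, tss_window = 100000L) {
  mid <- site_midpoint(sites)
  gene_id <- rep(NA_character_, nrow(sites))
  dist <- rep(NA_integer_, nrow(sites))
  ord <- order(genes$gene_id)     # lexicographic tie-break via stable which.min
  g <- genes[ord, , drop = FALSE]
  for (i in seq_len(nrow(sites))) {
    cand <- which(g$chrom == sites$chrom[[i]])
    if (!length(cand)) next
    d <- mid[[i]] - g$tss[cand]
    d <- ifelse(g$strand[cand] == "-", -d, d)
    j <- which.min(abs(d))
    if (abs(d[[j]]) <= tss_window) {
      gene_id[[i]] <- g$gene_id[[cand[[j]]]]
      dist[[i]] <- d[[j]]
    }
  }
  sites$gene_id <- gene_id
  sites$tss_distance <- dist
  sites
}

#' Classify sites into seven genomic location categories
#'
#' Categories, by site midpoint and with fixed precedence:
#' promoter/TSS (-1 kb to +100 bp of the TSS, strand-aware) > TTS
#' (within +/- 100 bp of the TTS) > 5'UTR > 3'UTR > exon > intron >
#' intergenic. UTRs require a coding span (thickStart < thickEnd) in the
#' gene model. Sites without an annotated gene are intergenic.
#'
#' @param sites data.frame with chrom, start, end, gene_id (as from
#'   [annotate_nearest_tss()]).
#' @param genes Gene-model data.frame.
#' @param promoter_up,promoter_down Promoter window around the TSS in bp.
#' @param tts_margin Half-width of the TTS window in bp.
#' @return Character vector of categories, one per site.
#' @export
genomic_category <- function(sites, genes, promoter_up = 1000L,
                             promoter_down = 100L, tts_margin = 100L) {
  mid <- site_midpoint(sites)
  gidx <- match(sites$gene_id, genes$gene_id)
  out <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    gi <- gidx[[i]]
    if (is.na(gi)) { out[[i]] <- "intergenic"; next }
    gn <- genes[gi, ]
    minus <- gn$strand == "-"
    d_tss <- if (minus) gn$tss - mid[[i]] else mid[[i]] - gn$tss
    if (d_tss >= -promoter_up && d_tss <= promoter_down) {
      out[[i]] <- "promoter/TSS"; next
    }
    if (abs(mid[[i]] - gn$tts) <= tts_margin) { out[[i]] <- "TTS"; next }
    if (mid[[i]] < gn$start || mid[[i]] >= gn$end) { out[[i]] <- "intergenic"; next }
    ex <- gn$exons[[1L]]
    in_exon <- any(mid[[i]] >= ex[, "start"] & mid[[i]] < ex[, "end"])
    if (!in_exon) { out[[i]] <- "intron"; next }
    has_cds <- gn$cds_start < gn$cds_end
    if (has_cds && mid[[i]] < gn$cds_start) {
      out[[i]] <- if (minus) "3'UTR" else "5'UTR"; next
    }
    if (has_cds && mid[[i]] >= gn$cds_end) {
      out[[i]] <- if (minus) "5'UTR" else "3'UTR"; next
    }
    out[[i]] <- "exon"
  }
  out
}

GENOMIC_CATEGORIES <- c("promoter/TSS", "5'UTR", "3'UTR", "exon", "intron",
                        "TTS", "intergenic")

MODE_LEVELS <- c("GAS", "ISRE", "NFKB", "GAS-ISRE", "GAS-NFKB", "ISRE-NFKB",
                 "GAS-ISRE-NFKB")

#' Gene-level binding-mode classification
#'
#' The mode of a gene is the set of motif classes with at least one
#' occupied, TSS-annotated site, written in canonical GAS/ISRE/NFKB order
#' (e.g. `"ISRE-NFKB"`). Genes with no occupied site receive no record.
#'
#' @param sites Occupied sites annotated to genes (columns motif_class,
#'   gene_id, tss_distance; rows with `NA` gene_id are dropped).
#' @param condition_pair Label for the condition pair, e.g. `"IFNa_LPS"`.
#' @return data.frame: gene_id, condition_pair, mode, n_sites,
#'   min_spacing (minimum distance between site midpoints of different
#'   classes, `NA` for single-class genes).
#' @export
classify_binding_mode <- function(sites, condition_pair) {
  sites <- sites[!is.na(sites$gene_id), , drop = FALSE]
  if (!nrow(sites)) {
    return(data.frame(gene_id = character(), condition_pair = character(),
                      mode = character(), n_sites = integer(),
                      min_spacing = integer(), stringsAsFactors = FALSE))
  }
  mid <- site_midpoint(sites)
  rows <- lapply(split(seq_len(nrow(sites)), sites$gene_id), function(idx) {
    cls <- unique(sites$motif_class[idx])
    cls <- MOTIF_CLASSES[MOTIF_CLASSES %in% cls]
    spacing <- NA_integer_
    if (length(cls) > 1L) {
      m <- mid[idx]; cl <- sites$motif_class[idx]
      d <- outer(m, m, function(x, y) abs(x - y))
      diffclass <- outer(cl, cl, "!=")
      spacing <- min(d[diffclass])
    }
    data.frame(gene_id = sites$gene_id[[idx[[1L]]]],
               condition_pair = condition_pair,
               mode = paste(cls, collapse = "-"),
               n_sites = length(idx), min_spacing = spacing,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-mode overlap between two condition pairs
#'
#' For each of the seven binding modes, the gene lists of the two
#' condition pairs are compared. The default percentage is the sum method
#' `100 * |A n B| / (|A| + |B|)`; jaccard is reported alongside.
#'
#' @param modes_a,modes_b Mode tables from [classify_binding_mode()].
#' @return data.frame: mode, n_a, n_b, n_common, pct_sum, pct_jaccard.
#' @export
mode_overlap_table <- function(modes_a, modes_b) {
  rows <- lapply(MODE_LEVELS, function(md) {
    a <- modes_a$gene_id[modes_a$mode == md]
    b <- modes_b$gene_id[modes_b$mode == md]
    data.frame(mode = md, n_a = length(a), n_b = length(b),
               n_common = length(intersect(a, b)),
               pct_sum = pairwise_overlap(a, b, "sum"),
               pct_jaccard = pairwise_overlap(a, b, "jaccard"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

peak_summits <- function(peaks) {
  data.frame(chrom = peaks$chrom, pos = peaks$start + peaks$summit_offset,
             stringsAsFactors = FALSE)
}

#' Distances between STAT1 summits and the closest p65 summits
#'
#' For every STAT1 peak summit, the signed distance (p65 summit minus
#' STAT1 summit, genome orientation) to the closest p65 summit on the same
#' chromosome. The histogram covers `[-half_window, +half_window)` in
#' `bin`-bp bins; out-of-range distances are excluded from the histogram
#' but retained in the distance list.
#'
#' @param stat1_peaks,p65_peaks Peak data.frames.
#' @param half_window Histogram half-width in bp.
#' @param bin Bin width in bp (must divide `2 * half_window`).
#' @return list(distances = integer vector, histogram = data.frame
#'   bin_start, bin_end, count).
#' @export
summit_distance_histogram <- function(stat1_peaks, p65_peaks,
                                      half_window = 1000L, bin = 25L) {
  if ((2L * half_window) %% bin != 0L) stopf("bin must divide 2 * half_window")
  s1 <- peak_summits(stat1_peaks)
  p6 <- peak_summits(p65_peaks)
  dists <- integer(0)
  for (ch in unique(s1$chrom)) {
    a <- s1$pos[s1$chrom == ch]
    b <- sort(p6$pos[p6$chrom == ch])
    if (!length(b)) next
    for (x in a) {
      d <- b - x
      dists <- c(dists, d[[which.min(abs(d))]])
    }
  }
  breaks <- seq(-half_window, half_window, by = bin)
  inrange <- dists[dists >= -half_window & dists < half_window]
  cnt <- if (length(inrange)) {
    tabulate(findInterval(inrange, breaks), nbins = length(breaks) - 1L)
  } else integer(length(breaks) - 1L)
  list(distances = dists,
       histogram = data.frame(bin_start = breaks[-length(breaks)],
                              bin_end = breaks[-1L], count = cnt))
}

# Overlap-weighted tag count of coverage intervals inside query regions.
coverage_region_sums <- function(cov, regions) {
  out <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    cc <- cov[cov$chrom == ch, , drop = FALSE]
    if (!nrow(cc)) next
    qry <- IRanges::IRanges(start = regions$start[ri] + 1L, end = regions$end[ri])
    sub <- IRanges::IRanges(start = cc$start + 1L, end = cc$end)
    ov <- IRanges::findOverlaps(qry, sub)
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(qry[qh], sub[sh])) /
      IRanges::width(sub[sh])
    contr <- w * cc$value[sh]
    agg <- tapply(contr, qh, sum)
    out[ri[as.integer(names(agg))]] <- as.numeric(agg)
  }
  out
}

kmeans_farthest_init <- function(x, k, seed) {
  set.seed(seed)
  n <- nrow(x)
  centers <- integer(k)
  centers[[1L]] <- sample.int(n, 1L)
  dmin <- rowSums(sweep(x, 2L, x[centers[[1L]], ], "-")^2)
  for (j in seq_len(k - 1L) + 1L) {
    centers[[j]] <- which.max(dmin)
    if (dmin[[centers[[j]]]] == 0)
      stopf("fewer than k = %d distinct occupancy profiles", k)
    dmin <- pmin(dmin, rowSums(sweep(x, 2L, x[centers[[j]], ], "-")^2))
  }
  x[centers, , drop = FALSE]
}

#' RPKM occupancy matrix, k-means clustering and read-density matrix
#'
#' RPKM = reads_in_region / ((region_len / 1000) * (total_reads / 1e6)),
#' computed per region per sample from the coverage tracks. Rows are
#' clustered by k-means on log2(RPKM + 1) with a deterministic
#' farthest-point initialization (first center drawn under `seed`),
#' Lloyd iterations capped at 300; an emptied cluster is re-seeded from
#' the row farthest from its center. The RD matrix holds depth-normalized
#' tag counts in `bin`-bp bins within +/- `half_window` of region centers.
#'
#' @param regions data.frame chrom, start, end (e.g. merged peak regions).
#' @param coverage Named list of bedGraph data.frames, one per sample.
#' @param k Number of clusters.
#' @param seed Seed for the initialization draw.
#' @param half_window,bin RD matrix geometry in bp.
#' @return list(rpkm = regions x samples matrix, cluster = integer vector
#'   in 1..k, rd = named list of regions x bins matrices, regions).
#' @export
rpkm_and_cluster <- function(regions, coverage, k = 10L, seed = 1L,
                             half_window = 1000L, bin = 25L) {
  if (k > nrow(regions))
    stopf("k = %d exceeds the number of regions (%d)", k, nrow(regions))
  totals <- vapply(coverage, function(cv) sum(cv$value), 0)
  if (any(totals <= 0)) warning("sample with zero total coverage")
  rpkm <- sapply(names(coverage), function(sm) {
    reads <- coverage_region_sums(coverage[[sm]], regions)
    len_kb <- (regions$end - regions$start) / 1000
    denom <- len_kb * (totals[[sm]] / 1e6)
    ifelse(denom > 0, reads / denom, 0)
  })
  rpkm <- matrix(rpkm, nrow = nrow(regions),
                 dimnames = list(NULL, names(coverage)))
  x <- log2(rpkm + 1)
  centers <- kmeans_farthest_init(x, k, seed)
  km <- suppressWarnings(
    stats::kmeans(x, centers = centers, iter.max = 300L, algorithm = "Lloyd"))
  for (rep in 1:5) {                      # re-seed emptied clusters
    empty <- which(km$size == 0L)
    if (!length(empty)) break
    cen <- km$centers
    for (e in empty) {
      far <- which.max(rowSums((x - cen[km$cluster, , drop = FALSE])^2))
      cen[e, ] <- x[far, ]
    }
    km <- suppressWarnings(
      stats::kmeans(x, centers = cen, iter.max = 300L, algorithm = "Lloyd"))
  }
  centers_mid <- (regions$start + regions$end) %/% 2L
  nb <- (2L * half_window) %/% bin
  rd <- lapply(names(coverage), function(sm) {
    m <- matrix(0, nrow(regions), nb)
    for (b in seq_len(nb)) {
      bs <- centers_mid - half_window + (b - 1L) * bin
      qb <- data.frame(chrom = regions$chrom, start = bs, end = bs + bin)
      m[, b] <- coverage_region_sums(coverage[[sm]], qb)
    }
    m / (totals[[sm]] / 1e6)
  })
  names(rd) <- names(coverage)
  list(rpkm = rpkm, cluster = km$cluster, rd = rd, regions = regions)
}
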