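# Two PWM-scanning dialects.
#
# 1. Genome-wide log-odds: score(w) = sum_i ln(p(b_i, i) / q(b_i)); windows
#    reaching the per-class motif score threshold (MST) on either strand are
#    hits. Natural log with a uniform background is the convention the
#    default thresholds (GAS 6, ISRE 6, NFKB 7) were calibrated against;
#    the log base is config-exposed.
# 2. Promoter matrix-similarity: raw(w) = sum_i p(b_i, i), min-max
#    normalized per matrix so the consensus scores 1 and the per-column
#    minimum scores 0; hits where similarity >= threshold (GAS/ISRE 0.85,
#    NFKB 0.90).
#
# N bases score as background in both dialects (log-odds contribution 0;
# similarity contribution = background-weighted mean column probability).

#' Parameters for genome-wide log-odds scanning
#'
#' @param mst Named numeric vector of per-class motif score thresholds.
#' @param background Base frequencies for A, C, G, T (must sum to 1).
#' @param both_strands Scan the reverse strand too?
#' @param log_base Base of the logarithm used for the odds ratio.
#' @return A `scan_params` list.
#' @export
scan_params <- function(mst = c(GAS = 6, ISRE = 6, NFKB = 7),
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        both_strands = TRUE,
                        log_base = exp(1)) {
  if (abs(sum(background) - 1) > 1e-8) stopf("background frequencies must sum to 1")
  if (any(!is.finite(mst))) stopf("MST values must be finite")
  list(mst = mst, background = background, both_strands = both_strands,
       log_base = log_base)
}

#' Parameters for promoter matrix-similarity scanning
#'
#' The promoter window is -950/+50 bp around the TSS, strand-aware
#' (1000 bp total).
#'
#' @param upstream Bases upstream of the TSS.
#' @param downstream Bases downstream of the TSS.
#' @param threshold Named per-class similarity thresholds in (0, 1].
#' @param both_strands Scan the reverse strand too?
#' @return A `promoter_scan_params` list.
#' @export
promoter_scan_params <- function(upstream = 950L, downstream = 50L,
                                 threshold = c(GAS = 0.85, ISRE = 0.85, NFKB = 0.90),
                                 both_strands = TRUE) {
  if (any(threshold <= 0 | threshold > 1)) stopf("similarity thresholds must be in (0, 1]")
  list(upstream = as.integer(upstream), downstream = as.integer(downstream),
       threshold = threshold, both_strands = both_strands)
}

BASE_CODE_LUT <- local({
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("ACGTNacgtn")] <- rep(1:5, 2L)
  lut
})

encode_seq <- function(sequence) {
  v <- BASE_CODE_LUT[utf8ToInt(sequence)]
  if (anyNA(v)) stopf("sequence contains characters outside A/C/G/T/N")
  v
}

#' Reverse complement of a DNA string
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(sequence) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", sequence))))
}

reverse_pwm_probs <- function(probs) {
  # reverse-complement: reverse columns, swap A<->T and C<->G rows
  probs[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(probs))), drop = FALSE]
}

# Sliding-window sum of a per-position, per-base lookup table.
# score_tab: 5 x L (row 5 = N); returns vector over all windows.
window_scores <- function(codes, score_tab) {
  L <- ncol(score_tab)
  nw <- length(codes) - L + 1L
  if (nw < 1L) return(numeric(0L))
  s <- numeric(nw)
  for (i in seq_len(L)) {
    s <- s + score_tab[codes[i:(i + nw - 1L)], i]
  }
  s
}

scan_one_strand <- function(codes, score_tab, threshold) {
  s <- window_scores(codes, score_tab)
  idx <- which(s >= threshold)
  list(idx = idx, score = s[idx])
}

#' Scan a sequence with a PWM using log-odds scoring
#'
#' Every window on the forward (and, by default, reverse) strand whose
#' log-odds score reaches the class MST is reported; reverse-strand hits
#' are given in forward-strand coordinates. Start positions are 0-based
#' half-open offsets into `sequence` (add the chromosome offset for
#' genomic coordinates).
#'
#' @param sequence DNA string.
#' @param pwm A `pwm` object.
#' @param params A [scan_params()] list.
#' @param chrom Chromosome name recorded in the hits.
#' @param offset Genomic coordinate of the first base of `sequence`.
#' @return data.frame of motif hits: pwm_id, motif_class, chrom, start,
#'   end, strand, log_odds.
#' @export
log_odds_scan <- function(sequence, pwm, params = scan_params(),
                          chrom = "chr", offset = 0L) {
  L <- ncol(pwm$probs)
  mst <- params$mst[[pwm$motif_class]]
  q <- params$background
  if (any(q == 0) && pwm$pseudocount == 0)
    stopf("zero background frequency with zero pseudocount")
  codes <- encode_seq(sequence)
  tab <- log(sweep(pwm$probs, 1L, q, "/"), base = params$log_base)
  tab <- rbind(tab, N = 0)            # N scores as background
  fwd <- scan_one_strand(codes, tab, mst)
  hits <- data.frame(start = fwd$idx - 1L, strand = rep("+", length(fwd$idx)),
                     log_odds = fwd$score)
  if (isTRUE(params$both_strands)) {
    rtab <- log(sweep(reverse_pwm_probs(pwm$probs), 1L, q, "/"),
                base = params$log_base)
    rtab <- rbind(rtab, N = 0)
    rev <- scan_one_strand(codes, rtab, mst)
    hits <- rbind(hits, data.frame(start = rev$idx - 1L,
                                   strand = rep("-", length(rev$idx)),
                                   log_odds = rev$score))
  }
  out <- data.frame(pwm_id = rep(pwm$pwm_id, nrow(hits)),
                    motif_class = rep(pwm$motif_class, nrow(hits)),
                    chrom = rep(chrom, nrow(hits)),
                    start = hits$start + as.integer(offset),
                    end = hits$start + as.integer(offset) + L,
                    strand = hits$strand,
                    log_odds = hits$log_odds,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a sequence with a PWM using min-max matrix similarity
#'
#' `raw(w) = sum_i p(b_i, i)`; `similarity = (raw - raw_min) /
#' (raw_max - raw_min)` with `raw_max`/`raw_min` from per-column maximum
#' and minimum probabilities. The consensus scores exactly 1.
#'
#' @param sequence DNA string.
#' @param pwm A `pwm` object.
#' @param threshold Minimum similarity reported.
#' @param both_strands Scan the reverse strand too?
#' @param chrom,offset As in [log_odds_scan()].
#' @return data.frame of motif hits with a `similarity` column.
#' @export
matrix_similarity_scan <- function(sequence, pwm, threshold = 0.85,
                                   both_strands = TRUE,
                                   chrom = "chr", offset = 0L) {
  L <- ncol(pwm$probs)
  cmax <- apply(pwm$probs, 2L, max)
  cmin <- apply(pwm$probs, 2L, min)
  denom <- sum(cmax) - sum(cmin)
  if (denom <= 0) stopf("degenerate PWM '%s': raw_max equals raw_min", pwm$pwm_id)
  codes <- encode_seq(sequence)
  sim_tab <- function(probs) {
    # per-window similarity is affine in the raw probability sum, so fold
    # the min-max normalization into the per-position table
    tab <- rbind(probs, N = colMeans(probs))   # N ~ background mean
    sweep(tab, 2L, cmin, "-") / denom
  }
  fwd <- scan_one_strand(codes, sim_tab(pwm$probs), threshold)
  hits <- data.frame(start = fwd$idx - 1L, strand = rep("+", length(fwd$idx)),
                     similarity = fwd$score)
  if (isTRUE(both_strands)) {
    rp <- reverse_pwm_probs(pwm$probs)
    rtab <- rbind(rp, N = colMeans(rp))
    rtab <- sweep(rtab, 2L, rev(cmin), "-") / denom
    rev <- scan_one_strand(codes, rtab, threshold)
    hits <- rbind(hits, data.frame(start = rev$idx - 1L,
                                   strand = rep("-", length(rev$idx)),
                                   similarity = rev$score))
  }
  out <- data.frame(pwm_id = rep(pwm$pwm_id, nrow(hits)),
                    motif_class = rep(pwm$motif_class, nrow(hits)),
                    chrom = rep(chrom, nrow(hits)),
                    start = hits$start + as.integer(offset),
                    end = hits$start + as.integer(offset) + L,
                    strand = hits$strand,
                    similarity = pmin(hits$similarity, 1),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strand-aware promoter window of a gene
#'
#' For a `+` strand gene the window is `[tss - upstream, tss + downstream)`;
#' for a `-` strand gene it is `[tss - downstream, tss + upstream)` in
#' forward genome coordinates, i.e. the mirrored stretch relative to the
#' direction of transcription. Windows are clipped to chromosome bounds.
#'
#' @param genes Gene-model data.frame.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param upstream,downstream Window extent around the TSS in bp.
#' @return data.frame gene_id, chrom, start, end.
#' @export
promoter_windows <- function(genes, chrom_lengths, upstream = 950L,
                             downstream = 50L) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  len <- chrom_lengths[genes$chrom]
  if (anyNA(len)) stopf("gene TSS on a chromosome absent from the genome")
  if (any(genes$tss < 0L | genes$tss >= len)) stopf("gene TSS outside the genome")
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0L, as.integer(start)),
             end = pmin(as.integer(len), as.integer(end)),
             stringsAsFactors = FALSE)
}

#' Per-gene promoter motif-class profile
#'
#' A motif class is present for a gene iff at least one matrix-similarity
#' hit of any PWM of that class falls inside the strand-aware promoter
#' window; genes with at least one class are partitioned into the seven
#' Venn regions over {GAS, ISRE, NFKB}.
#'
#' @param genes Gene-model data.frame.
#' @param genome Named character vector of chromosome sequences.
#' @param pwms List of `pwm` objects (several PWMs may share a class; a hit
#'   under any one of them counts).
#' @param params A [promoter_scan_params()] list.
#' @return list(presence = data.frame(gene_id, GAS, ISRE, NFKB),
#'   venn = named counts over the 7 non-empty class combinations).
#' @export
promoter_site_profile <- function(genes, genome, pwms,
                                  params = promoter_scan_params()) {
  win <- promoter_windows(genes, nchar(genome), params$upstream, params$downstream)
  pres <- matrix(FALSE, nrow(genes), 3L,
                 dimnames = list(genes$gene_id, MOTIF_CLASSES))
  for (i in seq_len(nrow(win))) {
    s <- substr(genome[[win$chrom[[i]]]], win$start[[i]] + 1L, win$end[[i]])
    for (p in pwms) {
      if (pres[i, p$motif_class]) next
      h <- matrix_similarity_scan(s, p, threshold = params$threshold[[p$motif_class]],
                                  both_strands = params$both_strands)
      if (nrow(h) > 0L) pres[i, p$motif_class] <- TRUE
    }
  }
  presence <- data.frame(gene_id = genes$gene_id, pres, stringsAsFactors = FALSE)
  venn <- venn_counts3(genes$gene_id[pres[, "GAS"]],
                       genes$gene_id[pres[, "ISRE"]],
                       genes$gene_id[pres[, "NFKB"]],
                       labels = MOTIF_CLASSES)
  list(presence = presence, venn = venn)
}
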