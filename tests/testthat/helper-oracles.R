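# Independent brute-force oracles and tiny fixture builders.

# Window-by-window, character-by-character log-odds scoring; scans the
# reverse strand by reverse-complementing each window and re-scoring it
# against the same matrix (independent of the vectorized scanner).
oracle_log_odds_hits <- function(sequence, pwm, mst, background = 0.25) {
  L <- ncol(pwm$probs)
  n <- nchar(sequence)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_window <- function(w) {
    s <- 0
    for (i in seq_len(L)) {
      b <- substr(w, i, i)
      s <- s + if (b == "N") 0 else log(pwm$probs[b, i] / background)
    }
    s
  }
  rows <- list()
  for (pos in seq_len(max(0L, n - L + 1L))) {
    w <- toupper(substr(sequence, pos, pos + L - 1L))
    s <- score_window(w)
    if (s >= mst)
      rows[[length(rows) + 1L]] <- data.frame(start = pos - 1L, strand = "+",
                                              log_odds = s)
    rcw <- paste(rev(comp[strsplit(w, "")[[1L]]]), collapse = "")
    s2 <- score_window(rcw)
    if (s2 >= mst)
      rows[[length(rows) + 1L]] <- data.frame(start = pos - 1L, strand = "-",
                                              log_odds = s2)
  }
  if (!length(rows))
    return(data.frame(start = integer(), strand = character(),
                      log_odds = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Per-base membership oracle for interval algebra on one chromosome.
oracle_interval_op <- function(a, b, op, maxlen = 1200L) {
  cover <- function(df) {
    v <- logical(maxlen)
    for (i in seq_len(nrow(df))) {
      if (df$end[[i]] > df$start[[i]])
        v[(df$start[[i]] + 1L):df$end[[i]]] <- TRUE
    }
    v
  }
  va <- cover(a); vb <- cover(b)
  v <- switch(op, intersect = va & vb, subtract = va & !vb, merge = va | vb)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = rep("chr1", sum(keep)),
             start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

random_intervals <- function(n, maxlen = 1000L) {
  s <- sample.int(maxlen - 10L, n, replace = TRUE) - 1L
  w <- sample.int(60L, n, replace = TRUE)
  data.frame(chrom = "chr1", start = s, end = pmin(s + w, maxlen),
             stringsAsFactors = FALSE)
}

random_pwm <- function(L, id = "rnd", class = "GAS", sharp = 5) {
  cnt <- matrix(stats::rexp(4 * L) * sharp, 4, L)
  pwm(round(cnt * 20) + 1, id = id, motif_class = class, pseudocount = 0)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Uniform 4-row count matrix whose consensus is the given string.
consensus_pwm <- function(consensus, class, dominant = 97, other = 1,
                          pseudocount = 1e-3) {
  bases <- c("A", "C", "G", "T")
  cols <- strsplit(consensus, "")[[1L]]
  cnt <- sapply(cols, function(b) ifelse(bases == b, dominant, other))
  pwm(cnt, id = paste0(class, "_cons"), motif_class = class,
      pseudocount = pseudocount)
}

# Tiny gene-model data.frame builder.
make_gene <- function(gene_id, chrom, start, end, strand,
                      cds_start = start, cds_end = start,
                      exons = cbind(start = start, end = end)) {
  g <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                  start = start, end = end,
                  cds_start = cds_start, cds_end = cds_end,
                  tss = if (strand == "+") start else end - 1L,
                  tts = if (strand == "+") end - 1L else start,
                  stringsAsFactors = FALSE)
  g$exons <- list(exons)
  g
}

make_peak <- function(chrom, start, end, factor, condition,
                      summit_offset = (end - start) %/% 2L, score = 100) {
  data.frame(chrom = chrom, start = start, end = end,
             summit_offset = summit_offset, factor = factor,
             condition = condition, score = score, stringsAsFactors = FALSE)
}

# Small shared simulation for tests that only need structure, not power.
small_sim_config <- function(seed = 11L, ...) {
  sim_config(n_chroms = 2L, chrom_length = 1500000L, n_genes = 60L,
             seed = seed, ...)
}
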