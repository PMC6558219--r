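# Readers and writers for the plain-text formats the pipeline touches.
# All genomic coordinates are 0-based half-open (BED convention) throughout
# the package; anything 1-based is formatting at the I/O boundary only.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

CONDITIONS <- c("control", "IFNa", "IFNg", "LPS", "IFNa_LPS", "IFNg_LPS")
CELL_TYPES <- c("VSMC", "MP", "DC")
MOTIF_CLASSES <- c("GAS", "ISRE", "NFKB")
FACTORS <- c("STAT1", "p65")

#' Read a genome from a FASTA file
#'
#' Sequences are case-folded to upper case and validated against the
#' A/C/G/T/N alphabet. Duplicate headers are rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of chromosome sequences (class `"genome"`).
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  dup <- nm[duplicated(nm)]
  if (length(dup)) stopf("duplicate FASTA header: %s", dup[[1L]])
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  bad <- vapply(seqs, function(s) grepl("[^ACGTN]", s), logical(1L))
  if (any(bad))
    stopf("non-DNA characters (other than N) in sequence: %s",
          paste(nm[bad], collapse = ", "))
  if (any(nchar(seqs) == 0L)) stopf("empty sequence in FASTA: %s", path)
  structure(seqs, class = "genome")
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::BStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d chromosome(s): %s\n", length(x),
              paste(sprintf("%s (%d bp)", names(x), nchar(x)), collapse = ", ")))
  invisible(x)
}

read_tsv_lines <- function(path) {
  lines <- readLines(path)
  lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
}

split_fields <- function(lines) strsplit(lines, "[ \t]+")

#' Read a peak set from BED6/narrowPeak
#'
#' Accepts 6-column BED or 10-column narrowPeak (summit offset from the
#' interval start in column 10). Six-column input gets the interval midpoint
#' `floor((end - start) / 2)` as summit offset. Output is sorted by
#' (chrom, start).
#'
#' @param path Path to the BED/narrowPeak file.
#' @param factor Label of the immunoprecipitated factor, e.g. `"STAT1"`.
#' @param condition Treatment condition label.
#' @return A data.frame of peaks: chrom, start, end, summit_offset, factor,
#'   condition, score (0-based half-open coordinates).
#' @export
read_narrowpeak <- function(path, factor, condition) {
  if (!file.exists(path)) stopf("peak file not found: %s", path)
  lines <- read_tsv_lines(path)
  fl <- split_fields(lines)
  nf <- lengths(fl)
  bad <- which(!(nf %in% c(6L, 10L)))
  if (length(bad))
    stopf("%s line %d: expected 6 or 10 columns, got %d", path, bad[[1L]], nf[bad[[1L]]])
  chrom <- vapply(fl, `[[`, "", 1L)
  start <- as.integer(vapply(fl, `[[`, "", 2L))
  end <- as.integer(vapply(fl, `[[`, "", 3L))
  if (anyNA(start) || anyNA(end))
    stopf("%s line %d: non-integer coordinate",
          path, which(is.na(start) | is.na(end))[[1L]])
  bad <- which(start >= end | start < 0L)
  if (length(bad))
    stopf("%s line %d: invalid interval [%d, %d)", path, bad[[1L]],
          start[bad[[1L]]], end[bad[[1L]]])
  score <- ifelse(nf >= 5L, as.numeric(vapply(fl, function(x) x[[min(5L, length(x))]], "")), 0)
  summit <- ifelse(nf == 10L,
                   as.integer(vapply(fl, function(x) x[[length(x)]], "")),
                   (end - start) %/% 2L)
  bad <- which(summit < 0L | summit >= end - start)
  if (length(bad))
    stopf("%s line %d: summit offset %d outside [0, %d)", path, bad[[1L]],
          summit[bad[[1L]]], end[bad[[1L]]] - start[bad[[1L]]])
  pk <- data.frame(chrom = chrom, start = start, end = end,
                   summit_offset = summit, factor = factor,
                   condition = condition, score = score,
                   stringsAsFactors = FALSE)
  pk <- pk[order(pk$chrom, pk$start), , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

#' Write a peak set as 10-column narrowPeak
#'
#' @param peaks Peak data.frame as returned by [read_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end,
                   name = sprintf("%s_%s_%d", peaks$factor, peaks$condition,
                                  seq_len(nrow(peaks))),
                   score = peaks$score, strand = ".",
                   signalValue = peaks$score, pValue = -1, qValue = -1,
                   peak = peaks$summit_offset)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED12
#'
#' Exons are reconstructed from blockSizes/blockStarts; TSS and TTS point
#' coordinates are derived from the strand (TSS = span start on `+`,
#' span end - 1 on `-`; TTS at the opposite end). thickStart/thickEnd are
#' kept as the coding span for UTR classification.
#'
#' @param path Path to a BED12 file.
#' @return A data.frame of gene models with a list-column `exons` of
#'   two-column (start, end) matrices.
#' @export
read_bed12 <- function(path) {
  if (!file.exists(path)) stopf("gene-model file not found: %s", path)
  lines <- read_tsv_lines(path)
  fl <- split_fields(lines)
  bad <- which(lengths(fl) != 12L)
  if (length(bad))
    stopf("%s line %d: expected 12 columns, got %d", path, bad[[1L]],
          lengths(fl)[bad[[1L]]])
  out <- vector("list", length(fl))
  for (i in seq_along(fl)) {
    f <- fl[[i]]
    start <- as.integer(f[[2L]]); end <- as.integer(f[[3L]])
    strand <- f[[6L]]
    if (!strand %in% c("+", "-"))
      stopf("%s line %d: unknown strand '%s'", path, i, strand)
    if (is.na(start) || is.na(end) || start >= end)
      stopf("%s line %d: invalid span", path, i)
    n_blocks <- as.integer(f[[10L]])
    sizes <- as.integer(strsplit(f[[11L]], ",")[[1L]])
    offs <- as.integer(strsplit(f[[12L]], ",")[[1L]])
    if (length(sizes) != n_blocks || length(offs) != n_blocks)
      stopf("%s line %d: blockCount disagrees with blockSizes/blockStarts", path, i)
    ex_start <- start + offs
    ex_end <- ex_start + sizes
    if (any(ex_end > end) || any(ex_start < start))
      stopf("%s line %d: blocks exceed gene span", path, i)
    if (is.unsorted(ex_start, strictly = TRUE) ||
        any(ex_start[-1L] < ex_end[-n_blocks]))
      stopf("%s line %d: blocks unsorted or overlapping", path, i)
    out[[i]] <- list(gene_id = f[[4L]], chrom = f[[1L]], strand = strand,
                     start = start, end = end,
                     cds_start = as.integer(f[[7L]]), cds_end = as.integer(f[[8L]]),
                     exons = cbind(start = ex_start, end = ex_end))
  }
  genes <- data.frame(
    gene_id = vapply(out, `[[`, "", "gene_id"),
    chrom = vapply(out, `[[`, "", "chrom"),
    strand = vapply(out, `[[`, "", "strand"),
    start = vapply(out, `[[`, 0L, "start"),
    end = vapply(out, `[[`, 0L, "end"),
    cds_start = vapply(out, `[[`, 0L, "cds_start"),
    cds_end = vapply(out, `[[`, 0L, "cds_end"),
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tts <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  genes$exons <- lapply(out, `[[`, "exons")
  genes
}

#' Write gene models as BED12
#'
#' @param genes Gene-model data.frame as returned by [read_bed12()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(genes, path) {
  rows <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    rows[[i]] <- paste(
      genes$chrom[[i]], genes$start[[i]], genes$end[[i]], genes$gene_id[[i]],
      0, genes$strand[[i]], genes$cds_start[[i]], genes$cds_end[[i]], "0",
      nrow(ex), paste0(paste(ex[, "end"] - ex[, "start"], collapse = ","), ","),
      paste0(paste(ex[, "start"] - genes$start[[i]], collapse = ","), ","),
      sep = "\t")
  }
  writeLines(rows, path)
  invisible(path)
}

#' Build a position weight matrix from base counts
#'
#' Probabilities are `(count + pseudocount) / (column total + 4 * pseudocount)`.
#'
#' @param counts 4 x L non-negative count matrix with rows A, C, G, T.
#' @param id Matrix identifier.
#' @param motif_class One of `"GAS"`, `"ISRE"`, `"NFKB"`.
#' @param pseudocount Pseudocount added per cell before normalization.
#' @return A `pwm` object.
#' @export
pwm <- function(counts, id, motif_class, pseudocount = 1e-3) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stopf("PWM '%s': expected 4 rows (A,C,G,T)", id)
  if (ncol(counts) < 4L) stopf("PWM '%s': motif length must be >= 4", id)
  if (any(counts < 0)) stopf("PWM '%s': negative counts", id)
  if (!motif_class %in% MOTIF_CLASSES)
    stopf("unknown motif class '%s'", motif_class)
  tot <- colSums(counts)
  if (any(tot + 4 * pseudocount <= 0))
    stopf("PWM '%s': all-zero column with zero pseudocount", id)
  probs <- sweep(counts + pseudocount, 2L, tot + 4 * pseudocount, "/")
  rownames(probs) <- c("A", "C", "G", "T")
  structure(list(pwm_id = id, motif_class = motif_class, probs = probs,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s), length %d, consensus %s\n",
              x$pwm_id, x$motif_class, ncol(x$probs), pwm_consensus(x)))
  invisible(x)
}

#' Consensus string of a PWM (argmax base per column)
#'
#' @param pwm A `pwm` object.
#' @return Character consensus string.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$probs)[apply(pwm$probs, 2L, which.max)], collapse = "")
}

#' Read a JASPAR-style position frequency matrix
#'
#' Accepts the bracketed JASPAR dialect (`A [ 3 10 ... ]`) or four plain
#' whitespace-separated count rows in A, C, G, T order, with an optional
#' `>` header carrying the matrix id.
#'
#' @param path Path to the PFM file.
#' @param motif_class Motif class label for the matrix.
#' @param pseudocount Pseudocount passed to [pwm()].
#' @return A `pwm` object.
#' @export
read_jaspar_pfm <- function(path, motif_class, pseudocount = 1e-3) {
  if (!file.exists(path)) stopf("PFM file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  id <- tools::file_path_sans_ext(basename(path))
  if (grepl("^>", lines[[1L]])) {
    id <- sub("^>\\s*", "", lines[[1L]])
    id <- strsplit(id, "\\s+")[[1L]][[1L]]
    lines <- lines[-1L]
  }
  if (length(lines) != 4L)
    stopf("%s: expected 4 count rows, got %d", path, length(lines))
  rows <- lapply(lines, function(ln) {
    ln <- sub("^\\s*[ACGTacgt]\\s*", "", ln)
    ln <- gsub("[][]", " ", ln)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])
  })
  if (anyNA(unlist(rows))) stopf("%s: non-numeric count", path)
  if (length(unique(lengths(rows))) != 1L)
    stopf("%s: ragged count rows (lengths %s)", path,
          paste(lengths(rows), collapse = ", "))
  pwm(do.call(rbind, rows), id = id, motif_class = motif_class,
      pseudocount = pseudocount)
}

#' Write a PWM's underlying probabilities as a JASPAR-style matrix
#'
#' @param x A `pwm` object.
#' @param path Output path.
#' @param scale Counts are written as `probs * scale`, rounded.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(x, path, scale = 100) {
  cnt <- round(x$probs * scale)
  lines <- c(sprintf(">%s %s", x$pwm_id, x$motif_class),
             sprintf("%s [ %s ]", rownames(cnt),
                     apply(cnt, 1L, paste, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a replicate-level count matrix with its sample sheet
#'
#' The counts TSV has gene ids in the first column and one column per
#' sample; the sample sheet TSV has columns sample, cell_type, condition,
#' replicate. Counts must be non-negative integers; missing values and
#' columns not described in the sheet are errors.
#'
#' @param counts_path Path to the counts TSV.
#' @param samples Either a path to the sample-sheet TSV or a data.frame.
#' @return A `count_matrix` object: list(counts, samples).
#' @export
read_count_matrix <- function(counts_path, samples) {
  if (is.character(samples)) {
    samples <- utils::read.delim(samples, stringsAsFactors = FALSE)
  }
  need <- c("sample", "cell_type", "condition", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stopf("sample sheet lacks column(s): %s", paste(miss, collapse = ", "))
  tab <- utils::read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- tab[[1L]]
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  extra <- setdiff(colnames(mat), samples$sample)
  absent <- setdiff(samples$sample, colnames(mat))
  if (length(extra) || length(absent))
    stopf("counts/sample-sheet mismatch%s%s",
          if (length(extra)) paste0("; columns not in sheet: ", paste(extra, collapse = ", ")) else "",
          if (length(absent)) paste0("; sheet samples missing from counts: ", paste(absent, collapse = ", ")) else "")
  mat <- mat[, samples$sample, drop = FALSE]
  count_matrix(mat, samples, gene_ids = gene_ids)
}

#' Construct a count matrix object
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param samples Sample sheet data.frame (sample, cell_type, condition,
#'   replicate).
#' @param gene_ids Optional gene ids (defaults to rownames).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, samples, gene_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids)) stopf("gene ids required")
  if (anyNA(counts)) stopf("missing count value (no imputation is performed)")
  if (any(counts < 0)) stopf("negative count value")
  if (any(counts != round(counts)))
    stopf("non-integer count value (counts must be raw integers)")
  if (anyDuplicated(samples$sample)) stopf("duplicate sample labels")
  if (ncol(counts) != nrow(samples)) stopf("counts/sample-sheet size mismatch")
  for (ct in unique(samples$cell_type)) {
    if (!any(samples$condition[samples$cell_type == ct] == "control"))
      stopf("cell type %s has no control sample", ct)
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- gene_ids
  colnames(counts) <- samples$sample
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%d cell types, %d conditions)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$cell_type)),
              length(unique(x$samples$condition))))
  invisible(x)
}

#' Write a count matrix and its sample sheet
#'
#' @param x A `count_matrix`.
#' @param counts_path Output path for the counts TSV.
#' @param samples_path Output path for the sample-sheet TSV.
#' @return `counts_path`, invisibly.
#' @export
write_count_matrix <- function(x, counts_path, samples_path) {
  tab <- data.frame(gene_id = rownames(x$counts), x$counts, check.names = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fl <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fl) < 3L)
  if (length(bad)) stopf("%s line %d: GMT rows need name, description, >= 1 member",
                         path, bad[[1L]])
  sets <- lapply(fl, function(f) structure(f[-(1:2)], description = f[[2L]]))
  names(sets) <- vapply(fl, `[[`, "", 1L)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors (optional `description`
#'   attributes are preserved).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    d <- attr(sets[[nm]], "description")
    if (is.null(d)) d <- nm
    paste(c(nm, d, as.character(sets[[nm]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path Path to a bedGraph file (0-based half-open intervals).
#' @return data.frame chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  lines <- read_tsv_lines(path)
  fl <- split_fields(lines)
  bad <- which(lengths(fl) != 4L)
  if (length(bad)) stopf("%s line %d: bedGraph rows have 4 columns", path, bad[[1L]])
  df <- data.frame(chrom = vapply(fl, `[[`, "", 1L),
                   start = as.integer(vapply(fl, `[[`, "", 2L)),
                   end = as.integer(vapply(fl, `[[`, "", 3L)),
                   value = as.numeric(vapply(fl, `[[`, "", 4L)),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end))
    stopf("%s line %d: empty interval", path, which(df$start >= df$end)[[1L]])
  df
}

#' Write a bedGraph coverage track
#'
#' @param df data.frame chrom, start, end, value.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(df, path) {
  utils::write.table(df[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
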