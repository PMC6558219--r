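# Seeded multi-omic simulator with planted ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# a uniform-background toy genome carrying consensus GAS/ISRE/NFKB motif
# instances planted per gene according to one of eight binding modes;
# negative-binomial expression counts for 3 cell types x 6 conditions with
# planted fold changes and super-additive synergy for a subset of genes;
# and STAT1/p65 peak sets plus per-sample tag coverage whose presence
# follows the treatment schedule.

#' Built-in GAS/ISRE/NFKB position weight matrices
#'
#' Sharp synthetic matrices (97:1:1:1 column counts) shipped with the
#' package; their consensus strings are what the simulator plants.
#'
#' @param pseudocount Pseudocount passed to [pwm()].
#' @return Named list of three `pwm` objects (GAS, ISRE, NFKB).
#' @export
builtin_pwms <- function(pseudocount = 1e-3) {
  dir <- system.file("extdata", "motifs", package = "sicobind")
  out <- lapply(MOTIF_CLASSES, function(cl) {
    read_jaspar_pfm(file.path(dir, sprintf("%s_synthetic.pfm", cl)),
                    motif_class = cl, pseudocount = pseudocount)
  })
  names(out) <- MOTIF_CLASSES
  out
}

SIM_MODES <- c("none", MODE_LEVELS)

#' Simulation configuration
#'
#' Defaults describe the study design the simulator emulates: 3 cell
#' types x 6 conditions (control, IFNa, IFNg, LPS, IFNa+LPS, IFNg+LPS)
#' x 3 replicates; composite motif spacing uniform in 38-264 bp; arm
#' effects of 3 log2 units; a 2 log2-unit super-additive synergy bonus for
#' SI genes; and a sub-additive combined response (0.9 x the strongest
#' single-arm fold change) for non-SI responders. Most genes (72%) carry
#' no planted motif or effect: median-of-ratios normalization assumes a
#' non-differential majority, as genome-wide expression data provide.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_genes Number of genes (split evenly across chromosomes).
#' @param mode_fractions Fractions per planted mode over the 8 classes
#'   (must sum to 1).
#' @param promoter_fraction Fraction of motif groups planted in the
#'   -950/+50 promoter window (the rest go distal).
#' @param distal_range Distance range (bp from TSS) for distal placement.
#' @param spacing_range Pairwise midpoint spacing range (bp) for composite
#'   motif groups.
#' @param base_mean Baseline expected count of an average gene.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param effect_ifn log2 fold change of STAT-class genes under IFN.
#' @param effect_lps log2 fold change of NFKB-class genes under LPS.
#' @param synergy_bonus log2 bonus over additivity for SI genes in
#'   combined conditions.
#' @param combo_damping Non-SI combined response as a fraction of the
#'   strongest single-arm fold change.
#' @param si_fraction Fraction of motif-bearing core genes planted as SI.
#' @param shared_fraction Fraction of motif-bearing genes whose effects
#'   are shared by all three cell types (the rest respond in one).
#' @param n_replicates Biological replicates per cell type x condition.
#' @param peak_width Width of simulated peaks in bp.
#' @param summit_jitter Maximum peak-summit offset from the planted motif
#'   midpoint in bp.
#' @param tag_depth Expected tags under one peak in its sample.
#' @param background_rate Expected background tags per 25-bp bin.
#' @param sequential_recruitment If `TRUE`, p65 peaks also appear at
#'   composite (STAT-class + NFKB) sites under IFN alone, emulating STAT1
#'   recruitment preceding p65.
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2L, chrom_length = 4000000L, n_genes = 300L,
                       mode_fractions = c(none = 0.72, GAS = 0.04, ISRE = 0.04,
                                          NFKB = 0.04, "GAS-ISRE" = 0.04,
                                          "GAS-NFKB" = 0.04, "ISRE-NFKB" = 0.04,
                                          "GAS-ISRE-NFKB" = 0.04),
                       promoter_fraction = 0.5,
                       distal_range = c(2000L, 10000L),
                       spacing_range = c(38L, 264L),
                       base_mean = 100, dispersion = 0.05,
                       effect_ifn = 3, effect_lps = 3,
                       synergy_bonus = 2, combo_damping = 0.9,
                       si_fraction = 0.4, shared_fraction = 0.8,
                       n_replicates = 3L,
                       peak_width = 200L, summit_jitter = 0L,
                       tag_depth = 300, background_rate = 0.5,
                       sequential_recruitment = TRUE,
                       seed = 42L) {
  cfg <- as.list(environment())
  if (abs(sum(mode_fractions) - 1) > 1e-8) stopf("mode fractions must sum to 1")
  if (!all(names(mode_fractions) %in% SIM_MODES))
    stopf("unknown mode in mode_fractions")
  if (spacing_range[[1L]] <= 0 || diff(spacing_range) < 0)
    stopf("spacing range must be positive")
  if (base_mean <= 0) stopf("base mean must be positive")
  if (dispersion < 0) stopf("dispersion must be non-negative")
  structure(cfg, class = "sim_config")
}

mode_classes <- function(mode) {
  if (mode == "none") character(0) else strsplit(mode, "-", fixed = TRUE)[[1L]]
}

#' Simulate a toy genome with planted motif instances
#'
#' Background sequence is i.i.d. uniform over A/C/G/T. Genes are placed on
#' an even grid with disjoint motif territories; each gene's planted mode
#' writes the corresponding PWM consensus strings into its promoter
#' (-950/+50) or a distal position, composite groups spaced so every
#' pairwise midpoint distance falls in `spacing_range`.
#'
#' @param config A [sim_config()].
#' @param pwms PWMs whose consensus strings are planted.
#' @return list(genome, genes, truth): the genome, the gene models, and a
#'   `sim_truth` with planted modes, motif coordinates, SI flags and
#'   expected log2 fold changes.
#' @export
simulate_genome <- function(config = sim_config(), pwms = builtin_pwms()) {
  set.seed(config$seed)
  gene_len <- 3000L
  per_chrom <- ceiling(config$n_genes / config$n_chroms)
  slot <- config$chrom_length %/% (per_chrom + 1L)
  territory <- max(config$distal_range) + 1500L
  if (slot < 2L * territory + gene_len)
    stopf(paste("genes do not fit: %d genes need slots of >= %d bp;",
                "increase chrom_length or decrease n_genes"),
          config$n_genes, 2L * territory + gene_len)
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  genome <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
          collapse = "")
  }, "")
  names(genome) <- chroms

  n <- config$n_genes
  pool <- rep(names(config$mode_fractions),
              times = round(config$mode_fractions * n))
  if (length(pool) < n) pool <- c(pool, rep("none", n - length(pool)))
  modes <- sample(pool[seq_len(n)])
  gene_id <- sprintf("gene%03d", seq_len(n))
  chrom <- chroms[((seq_len(n) - 1L) %/% per_chrom) + 1L]
  slot_idx <- ((seq_len(n) - 1L) %% per_chrom) + 1L
  start <- as.integer(slot_idx * slot - gene_len %/% 2L)
  end <- start + gene_len
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", start, end - 1L)
  # two exons with a coding span leaving UTRs at both ends
  exons <- lapply(seq_len(n), function(i)
    cbind(start = c(start[[i]], start[[i]] + 2400L),
          end = c(start[[i]] + 400L, end[[i]])))
  genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      start = start, end = end,
                      cds_start = start + 200L, cds_end = end - 200L,
                      tss = tss, tts = ifelse(strand == "+", end - 1L, start),
                      stringsAsFactors = FALSE)
  genes$exons <- exons

  consensus <- vapply(pwms, pwm_consensus, "")
  motif_rows <- list()
  for (i in seq_len(n)) {
    cls <- mode_classes(modes[[i]])
    if (!length(cls)) next
    lens <- nchar(consensus[cls])
    m <- length(cls)
    gaps <- if (m > 1L) {
      hi <- config$spacing_range[[2L]] / (m - 1L)
      lo <- min(config$spacing_range[[1L]], hi)
      round(stats::runif(m - 1L, lo, hi))
    } else integer(0)
    # midpoint offsets within the group
    mids <- cumsum(c(0, gaps))
    starts_rel <- as.integer(mids - lens %/% 2L)
    starts_rel <- starts_rel - min(starts_rel)
    group_len <- max(starts_rel + lens)
    in_promoter <- stats::runif(1L) < config$promoter_fraction
    if (in_promoter) {
      lo_anchor <- if (strand[[i]] == "+") tss[[i]] - 950L else tss[[i]] - 50L
      anchor <- lo_anchor + sample.int(1000L - group_len, 1L) - 1L
    } else {
      d <- round(stats::runif(1L, config$distal_range[[1L]],
                              config$distal_range[[2L]]))
      side <- sample(c(-1L, 1L), 1L)
      anchor <- tss[[i]] + side * d
      anchor <- max(1L, min(anchor, config$chrom_length - group_len - 1L))
    }
    for (j in seq_len(m)) {
      s <- anchor + starts_rel[[j]]
      e <- s + lens[[j]]
      substr(genome[[chrom[[i]]]], s + 1L, e) <- consensus[[cls[[j]]]]
      motif_rows[[length(motif_rows) + 1L]] <-
        data.frame(gene_id = gene_id[[i]], motif_class = cls[[j]],
                   chrom = chrom[[i]], start = s, end = e,
                   promoter = in_promoter, stringsAsFactors = FALSE)
    }
  }
  motifs <- if (length(motif_rows)) do.call(rbind, motif_rows) else
    data.frame(gene_id = character(), motif_class = character(),
               chrom = character(), start = integer(), end = integer(),
               promoter = logical())

  motif_bearing <- gene_id[modes != "none"]
  n_core <- round(config$shared_fraction * length(motif_bearing))
  core <- sort(sample(motif_bearing, n_core))
  solo_cell <- stats::setNames(sample(CELL_TYPES, length(motif_bearing),
                                      replace = TRUE), motif_bearing)
  si_genes <- sort(sample(core, round(config$si_fraction * length(core))))

  gene_tab <- data.frame(gene_id = gene_id, mode = modes,
                         si = gene_id %in% si_genes,
                         core = gene_id %in% core,
                         stringsAsFactors = FALSE)
  truth <- structure(
    list(genes = gene_tab, motifs = motifs, solo_cell = solo_cell,
         expected_log2fc = expected_log2fc_table(gene_tab, solo_cell, config),
         config = config),
    class = "sim_truth")
  list(genome = structure(genome, class = "genome"), genes = genes,
       truth = truth)
}

# Planted expected log2 FC per gene x cell type x condition.
expected_log2fc_table <- function(gene_tab, solo_cell, config) {
  rows <- list()
  for (i in seq_len(nrow(gene_tab))) {
    g <- gene_tab$gene_id[[i]]
    cls <- mode_classes(gene_tab$mode[[i]])
    for (ct in CELL_TYPES) {
      active <- length(cls) > 0 &&
        (gene_tab$core[[i]] || identical(unname(solo_cell[g]), ct))
      a <- if (active && any(cls %in% c("GAS", "ISRE"))) config$effect_ifn else 0
      l <- if (active && "NFKB" %in% cls) config$effect_lps else 0
      combo <- if (!active || (a == 0 && l == 0)) 0
        else if (gene_tab$si[[i]])
          log2(2^a + 2^l) + config$synergy_bonus
        else log2(config$combo_damping) + max(a, l)
      lfc <- c(control = 0, IFNa = a, IFNg = a, LPS = l,
               IFNa_LPS = combo, IFNg_LPS = combo)
      rows[[paste(g, ct)]] <- data.frame(
        gene_id = g, cell_type = ct, condition = names(lfc),
        log2fc = unname(lfc), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d genes (%d motif-bearing, %d SI), %d planted motifs\n",
              nrow(x$genes), sum(x$genes$mode != "none"), sum(x$genes$si),
              nrow(x$motifs)))
  invisible(x)
}

#' Simulate replicate-level expression counts
#'
#' Counts are negative binomial with mean
#' `gene_baseline * 2^planted_log2fc * sample_size_factor` and dispersion
#' from the configuration. SI genes receive the super-additive combined
#' mean; the shared core responds in all three cell types.
#'
#' @param truth A `sim_truth` from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return A `count_matrix` with an attribute `"size_factors"` holding the
#'   planted per-sample factors.
#' @export
simulate_expression <- function(truth, config = truth$config) {
  if (config$base_mean <= 0) stopf("base mean must be positive")
  set.seed(config$seed + 1L)
  gene_ids <- truth$genes$gene_id
  n <- length(gene_ids)
  baseline <- config$base_mean * 2^stats::runif(n, -1, 1)
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         condition = CONDITIONS, cell_type = CELL_TYPES,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("cell_type", "condition", "replicate")]
  samples$sample <- sprintf("%s_%s_r%d", samples$cell_type,
                            samples$condition, samples$replicate)
  sf <- stats::runif(nrow(samples), 0.7, 1.3)
  lfc <- truth$expected_log2fc
  key <- paste(lfc$gene_id, lfc$cell_type, lfc$condition)
  lfc_lookup <- stats::setNames(lfc$log2fc, key)
  counts <- matrix(0L, n, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    mu <- baseline *
      2^lfc_lookup[paste(gene_ids, samples$cell_type[[j]], samples$condition[[j]])] *
      sf[[j]]
    counts[, j] <- if (config$dispersion > 0) {
      stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
    } else {
      stats::rpois(n, mu)
    }
  }
  cm <- count_matrix(counts, samples, gene_ids = gene_ids)
  attr(cm, "size_factors") <- stats::setNames(sf, samples$sample)
  cm
}

# Which factor x condition combinations carry a peak over a given motif.
peak_schedule <- function(motif_class, gene_mode, sequential) {
  cls <- mode_classes(gene_mode)
  composite <- "NFKB" %in% cls && any(cls %in% c("GAS", "ISRE"))
  if (motif_class %in% c("GAS", "ISRE")) {
    list(factor = "STAT1", conditions = c("IFNa", "IFNg", "IFNa_LPS", "IFNg_LPS"))
  } else {
    conds <- c("LPS", "IFNa_LPS", "IFNg_LPS")
    if (sequential && composite) conds <- c("IFNa", "IFNg", conds)
    list(factor = "p65", conditions = conds)
  }
}

#' Simulate ChIP peaks and tag coverage
#'
#' STAT1 peaks are placed over planted GAS/ISRE motifs in IFN and IFN+LPS
#' conditions; p65 peaks over planted NFKB motifs in LPS and IFN+LPS
#' conditions and, when `sequential_recruitment` is on, at composite sites
#' under IFN alone. Summits sit at the planted motif midpoint, jittered by
#' at most `summit_jitter` bp. Coverage is Poisson: a flat background plus
#' a Gaussian-shaped tag pile under each peak present in that sample,
#' binned at 25 bp over the peak neighborhoods.
#'
#' @param truth A `sim_truth` from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return list(peaks = peak data.frame over all factor x condition sets,
#'   coverage = named list of 12 bedGraph data.frames
#'   (factor_condition), truth_peaks = per-motif schedule table).
#' @export
simulate_chip <- function(truth, config = truth$config) {
  set.seed(config$seed + 2L)
  bin <- 25L
  motifs <- truth$motifs
  mode_of <- stats::setNames(truth$genes$mode, truth$genes$gene_id)
  w <- config$peak_width
  peak_rows <- list()
  for (i in seq_len(nrow(motifs))) {
    sch <- peak_schedule(motifs$motif_class[[i]], mode_of[[motifs$gene_id[[i]]]],
                         config$sequential_recruitment)
    mid <- (motifs$start[[i]] + motifs$end[[i]]) %/% 2L
    for (cd in sch$conditions) {
      jit <- if (config$summit_jitter > 0)
        sample(seq(-config$summit_jitter, config$summit_jitter), 1L) else 0L
      summit <- mid + jit
      start <- summit - w %/% 2L
      # peak always contains its motif interval
      start <- min(start, motifs$start[[i]])
      end <- max(start + w, motifs$end[[i]])
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        chrom = motifs$chrom[[i]], start = start, end = end,
        summit_offset = summit - start, factor = sch$factor, condition = cd,
        score = round(stats::runif(1L, 50, 200)),
        gene_id = motifs$gene_id[[i]], motif_class = motifs$motif_class[[i]],
        stringsAsFactors = FALSE)
    }
  }
  peaks <- if (length(peak_rows)) do.call(rbind, peak_rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               summit_offset = integer(), factor = character(),
               condition = character(), score = numeric(),
               gene_id = character(), motif_class = character())
  peaks <- peaks[order(peaks$factor, peaks$condition, peaks$chrom, peaks$start), ]
  rownames(peaks) <- NULL

  # binned coverage over motif neighborhoods (identical bins across samples)
  if (!nrow(motifs))
    return(list(peaks = peaks, coverage = list()))
  nb_half <- 1200L
  neigh <- data.frame(chrom = motifs$chrom,
                      start = pmax(0L, ((motifs$start - nb_half) %/% bin) * bin),
                      end = (motifs$end + nb_half) %/% bin * bin + bin)
  neigh <- interval_ops(neigh, NULL, "merge")
  bins <- do.call(rbind, lapply(seq_len(nrow(neigh)), function(i) {
    bs <- seq(neigh$start[[i]], neigh$end[[i]] - bin, by = bin)
    data.frame(chrom = neigh$chrom[[i]], start = bs, end = bs + bin,
               stringsAsFactors = FALSE)
  }))
  sigma <- 75
  height <- config$tag_depth * bin / (sigma * sqrt(2 * pi))
  coverage <- list()
  for (fac in FACTORS) {
    for (cd in CONDITIONS) {
      mu <- rep(config$background_rate, nrow(bins))
      pk <- peaks[peaks$factor == fac & peaks$condition == cd, , drop = FALSE]
      for (i in seq_len(nrow(pk))) {
        summit <- pk$start[[i]] + pk$summit_offset[[i]]
        sel <- which(bins$chrom == pk$chrom[[i]] &
                       bins$start >= summit - nb_half &
                       bins$end <= summit + nb_half + bin)
        d <- (bins$start[sel] + bin / 2) - summit
        mu[sel] <- mu[sel] + height * exp(-d^2 / (2 * sigma^2))
      }
      cov <- bins
      cov$value <- stats::rpois(nrow(bins), mu)
      coverage[[sprintf("%s_%s", fac, cd)]] <- cov
    }
  }
  list(peaks = peaks, coverage = coverage)
}

#' Run the full simulator
#'
#' @param config A [sim_config()].
#' @param pwms PWMs whose consensus strings are planted.
#' @return A `sim_study` list: genome, genes, truth, counts, peaks,
#'   coverage, config.
#' @export
simulate_study <- function(config = sim_config(), pwms = builtin_pwms()) {
  g <- simulate_genome(config, pwms)
  counts <- simulate_expression(g$truth, config)
  chip <- simulate_chip(g$truth, config)
  structure(list(genome = g$genome, genes = g$genes, truth = g$truth,
                 counts = counts, peaks = chip$peaks,
                 coverage = chip$coverage, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %d chroms, %d genes, %d samples, %d peaks, seed %d\n",
              length(x$genome), nrow(x$genes), ncol(x$counts$counts),
              nrow(x$peaks), x$config$seed))
  invisible(x)
}

#' Write all simulator outputs to a directory
#'
#' Emits FASTA, BED12, one narrowPeak per factor x condition, one bedGraph
#' per sample, the counts TSV + sample sheet, and a truth TSV.
#'
#' @param study A `sim_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(study$genome, file.path(dir, "genome.fa"))
  write_bed12(study$genes, file.path(dir, "genes.bed"))
  write_count_matrix(study$counts, file.path(dir, "counts.tsv"),
                     file.path(dir, "samples.tsv"))
  for (fac in unique(study$peaks$factor)) {
    for (cd in unique(study$peaks$condition)) {
      pk <- study$peaks[study$peaks$factor == fac & study$peaks$condition == cd, ]
      if (nrow(pk))
        write_narrowpeak(pk, file.path(dir, sprintf("peaks_%s_%s.narrowPeak",
                                                    fac, cd)))
    }
  }
  for (sm in names(study$coverage))
    write_bedgraph(study$coverage[[sm]], file.path(dir, sprintf("coverage_%s.bedGraph", sm)))
  utils::write.table(study$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth$motifs, file.path(dir, "truth_motifs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
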