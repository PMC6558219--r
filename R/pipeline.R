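# Configuration-driven end-to-end runs: simulate (or load) inputs,
# run the expression and ChIP-integration analyses, and write
# machine-readable outputs plus a human-readable report.

#' Build and validate a pipeline configuration
#'
#' A configuration either names input files (genome FASTA, BED12 gene
#' models, counts TSV + sample sheet, narrowPeak files with factor and
#' condition labels, PFM files, optional GMT) or carries a `simulate`
#' block of [sim_config()] arguments. All thresholds live under `params`.
#'
#' @param x Path to a YAML file, or a list with elements `simulate`
#'   and/or `inputs`, optional `params`, and `outdir`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stopf("config needs either a 'simulate' block or an 'inputs' block")
  if (is.null(cfg$outdir)) stopf("config needs an 'outdir'")
  if (!is.null(cfg$inputs)) {
    need <- c("genome", "genes", "counts", "samples")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss))
      stopf("inputs block lacks: %s", paste(miss, collapse = ", "))
    paths <- c(unlist(cfg$inputs[need]),
               vapply(cfg$inputs$peaks, `[[`, "", "path"),
               vapply(cfg$inputs$coverage, function(z)
                 if (is.list(z)) z$path else z, ""))
    absent <- paths[!file.exists(paths)]
    if (length(absent)) stopf("input file not found: %s", absent[[1L]])
  }
  defaults <- list(fc_cutoff = 2, strict_fc = FALSE, expression_cutoff = 8,
                   epsilon = 0.5,
                   mst = c(GAS = 6, ISRE = 6, NFKB = 7),
                   similarity = c(GAS = 0.85, ISRE = 0.85, NFKB = 0.90),
                   promoter_up = 950L, promoter_down = 50L,
                   tss_window = 100000L, kmeans_k = 10L, kmeans_seed = 1L,
                   hist_half_window = 1000L, hist_bin = 25L)
  p <- utils::modifyList(defaults, cfg$params %||% list())
  if (p$fc_cutoff <= 0 || p$expression_cutoff < 0 || p$tss_window <= 0 ||
      any(p$mst > 50) || any(p$similarity <= 0 | p$similarity > 1))
    stopf("pipeline parameter out of its documented range")
  cfg$params <- p
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, ...) message(sprintf("[%s] ", name), sprintf(...))

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (isTRUE(sim_args)) sim_args <- list()
    cfg <- do.call(sim_config, sim_args)
    stage("simulate", "seed %d: generating genome, counts, peaks", cfg$seed)
    study <- simulate_study(cfg)
    list(genome = study$genome, genes = study$genes, counts = study$counts,
         peaks = study$peaks, coverage = study$coverage,
         pwms = builtin_pwms(), truth = study$truth,
         gene_sets = NULL)
  } else {
    ins <- config$inputs
    peaks <- do.call(rbind, lapply(ins$peaks, function(p)
      read_narrowpeak(p$path, p$factor, p$condition)))
    coverage <- lapply(ins$coverage, function(z)
      read_bedgraph(if (is.list(z)) z$path else z))
    pwms <- if (is.null(ins$motifs)) builtin_pwms() else
      lapply(ins$motifs, function(m) read_jaspar_pfm(m$path, m$class))
    list(genome = read_genome_fasta(ins$genome),
         genes = read_bed12(ins$genes),
         counts = read_count_matrix(ins$counts, ins$samples),
         peaks = peaks, coverage = coverage, pwms = pwms, truth = NULL,
         gene_sets = if (is.null(ins$gene_sets)) NULL else read_gmt(ins$gene_sets))
  }
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stages, in order: expression records and up lists; three-cell-type Venn
#' intersections per combined condition; SI records; promoter site
#' profiles; genome-wide motif scan; occupied-site catalog, nearest-TSS
#' annotation and genomic categories; binding-mode tables and
#' cross-condition mode overlaps; summit-distance histograms; RPKM
#' occupancy clustering; and a JSON summary. On simulated input a
#' recovery report against the planted truth is added. Deterministic
#' under a fixed seed; any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()] (or something coercible to one).
#' @return Invisibly, a list with the summary and the main result tables;
#'   files are written under `config$outdir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  p <- config$params
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  inp <- load_pipeline_inputs(config)

  ## expression
  stage("expression", "%d genes x %d samples", nrow(inp$counts$counts),
        ncol(inp$counts$counts))
  sf <- size_factors(inp$counts)
  norm <- normalize_and_filter(inp$counts, sf, cutoff = p$expression_cutoff)
  records <- fold_changes(norm, fc_cutoff = p$fc_cutoff,
                          strict_cutoff = p$strict_fc, epsilon = p$epsilon)
  write_tsv(records, out("expression_records.tsv"))
  ups <- up_regulated_lists(records)
  stage("expression", "up-regulated lists per cell type x condition written")

  combos <- intersect(c("IFNa_LPS", "IFNg_LPS"),
                      unique(inp$counts$samples$condition))
  cell_types <- unique(inp$counts$samples$cell_type)
  venn <- list(); common <- list()
  if (length(cell_types) == 3L) {
    for (cb in combos) {
      lists <- lapply(cell_types, function(ct) ups[[ct]][[cb]])
      names(lists) <- cell_types
      cg <- common_genes(lists)
      common[[cb]] <- cg$common
      venn[[cb]] <- cg$venn
      stage("venn", "%s: %d genes common to all three cell types", cb,
            length(cg$common))
    }
    write_tsv(data.frame(condition = rep(names(venn), each = 7L),
                         region = unlist(lapply(venn, names)),
                         count = unlist(venn)),
              out("venn_counts.tsv"))
  }
  si <- si_flags(records)
  if (!is.null(si)) {
    write_tsv(si, out("si_records.tsv"))
    stage("si", "%d of %d records SI-flagged", sum(si$si_flag), nrow(si))
  }

  ## promoter profiles
  prof <- promoter_site_profile(
    inp$genes, inp$genome, inp$pwms,
    promoter_scan_params(p$promoter_up, p$promoter_down, p$similarity))
  write_tsv(prof$presence, out("promoter_sites.tsv"))
  stage("promoter", "%d genes with >= 1 promoter site",
        sum(rowSums(prof$presence[, MOTIF_CLASSES]) > 0))

  ## gene-set enrichment (optional)
  enrichment <- NULL
  if (!is.null(inp$gene_sets) && length(common)) {
    universe <- rownames(inp$counts$counts)
    enrichment <- enrich_gene_sets(common[[1L]], universe, inp$gene_sets)
    write_tsv(enrichment, out("enrichment.tsv"))
  }

  ## genome-wide motif scan
  sp <- scan_params(mst = p$mst)
  hits <- do.call(rbind, lapply(names(inp$genome), function(ch) {
    do.call(rbind, lapply(inp$pwms, function(pw)
      log_odds_scan(inp$genome[[ch]], pw, sp, chrom = ch)))
  }))
  stage("scan", "%d motif hits at MST (GAS %g, ISRE %g, NFKB %g)",
        nrow(hits), p$mst[["GAS"]], p$mst[["ISRE"]], p$mst[["NFKB"]])
  write_tsv(hits, out("motif_hits.tsv"))

  ## occupancy, annotation, modes
  mode_tables <- list()
  site_catalogs <- list()
  for (cb in combos) {
    occ <- occupied_sites(hits, inp$peaks, cb)
    occ <- annotate_nearest_tss(occ, inp$genes, p$tss_window)
    occ <- occ[!is.na(occ$gene_id), , drop = FALSE]
    occ$category <- genomic_category(occ, inp$genes)
    site_catalogs[[cb]] <- occ
    mode_tables[[cb]] <- classify_binding_mode(occ, cb)
    stage("modes", "%s: %d occupied sites over %d genes", cb, nrow(occ),
          nrow(mode_tables[[cb]]))
  }
  if (length(site_catalogs)) {
    write_tsv(do.call(rbind, lapply(combos, function(cb)
      cbind(condition_pair = cb, site_catalogs[[cb]]))),
      out("occupied_sites.tsv"))
    write_tsv(do.call(rbind, mode_tables), out("binding_modes.tsv"))
  }
  overlap <- NULL
  if (length(mode_tables) == 2L) {
    overlap <- mode_overlap_table(mode_tables[[1L]], mode_tables[[2L]])
    write_tsv(overlap, out("mode_overlap.tsv"))
  }

  ## summit distances
  hist_tabs <- list()
  for (cb in combos) {
    s1 <- inp$peaks[inp$peaks$factor == "STAT1" & inp$peaks$condition == cb, ]
    p6 <- inp$peaks[inp$peaks$factor == "p65" & inp$peaks$condition == cb, ]
    if (nrow(s1) && nrow(p6)) {
      hist_tabs[[cb]] <- summit_distance_histogram(
        s1, p6, p$hist_half_window, p$hist_bin)
      write_tsv(hist_tabs[[cb]]$histogram,
                out(sprintf("summit_histogram_%s.tsv", cb)))
    }
  }

  ## occupancy clustering
  occmat <- NULL
  if (length(inp$coverage)) {
    regions <- interval_ops(inp$peaks[, c("chrom", "start", "end")], NULL, "merge")
    k <- min(p$kmeans_k, nrow(regions))
    occmat <- rpkm_and_cluster(regions, inp$coverage, k = k,
                               seed = p$kmeans_seed,
                               half_window = p$hist_half_window,
                               bin = p$hist_bin)
    write_tsv(cbind(regions, cluster = occmat$cluster,
                    as.data.frame(occmat$rpkm)),
              out("occupancy_matrix.tsv"))
    stage("cluster", "%d regions in %d clusters", nrow(regions), k)
  }

  ## summary + recovery
  summary <- list(
    n_genes = nrow(inp$counts$counts),
    n_samples = ncol(inp$counts$counts),
    up_counts = lapply(ups, function(l) lapply(l, length)),
    venn = lapply(venn, as.list),
    common_counts = lapply(common, length),
    si_flagged = sum(si$si_flag),
    si_records = nrow(si),
    promoter_venn = as.list(prof$venn),
    mode_counts = lapply(mode_tables, function(m) as.list(table(m$mode))),
    mode_overlap_pct_sum =
      if (is.null(overlap)) NULL else
        as.list(stats::setNames(round(overlap$pct_sum, 2), overlap$mode)))
  if (!is.null(inp$truth)) {
    summary$recovery <- recovery_report(inp$truth, mode_tables, si, combos)
    stage("recovery", "mode accuracy %.1f%%, SI sens %.1f%% spec %.1f%%",
          summary$recovery$mode_accuracy_pct,
          summary$recovery$si_sensitivity_pct,
          summary$recovery$si_specificity_pct)
  }
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(summary = summary, records = records, si = si,
                 modes = mode_tables, overlap = overlap,
                 promoter = prof, histograms = hist_tabs,
                 occupancy = occmat, truth = inp$truth,
                 outdir = config$outdir))
}

#' Recovery metrics of a run against planted truth
#'
#' Mode accuracy is the fraction of motif-bearing genes whose classified
#' mode in a combined condition equals the planted mode; SI sensitivity
#' and specificity compare SI flags in the reference cell type (VSMC)
#' against planted synergy flags.
#'
#' @param truth A `sim_truth`.
#' @param mode_tables Named list of mode tables per combined condition.
#' @param si SI records from [si_flags()].
#' @param combos Combined-condition labels evaluated.
#' @return list of percentage metrics.
#' @export
recovery_report <- function(truth, mode_tables, si, combos) {
  tg <- truth$genes[truth$genes$mode != "none", , drop = FALSE]
  correct <- 0L; total <- 0L
  for (cb in combos) {
    mt <- mode_tables[[cb]]
    pred <- stats::setNames(mt$mode, mt$gene_id)
    total <- total + nrow(tg)
    correct <- correct + sum(!is.na(pred[tg$gene_id]) &
                               pred[tg$gene_id] == tg$mode)
  }
  svsmc <- si[si$cell_type == "VSMC", , drop = FALSE]
  truth_si <- stats::setNames(truth$genes$si, truth$genes$gene_id)
  flag <- svsmc$si_flag
  tr <- truth_si[svsmc$gene_id]
  sens <- if (any(tr)) 100 * sum(flag & tr) / sum(tr) else NA_real_
  spec <- if (any(!tr)) 100 * sum(!flag & !tr) / sum(!tr) else NA_real_
  list(mode_accuracy_pct = 100 * correct / total,
       si_sensitivity_pct = sens,
       si_specificity_pct = spec,
       n_motif_genes = nrow(tg))
}

#' Render a human-readable report from a pipeline summary
#'
#' Tabulates Venn, mode and overlap counts, SI tallies (including the
#' packaged top-30 fold-change fixtures) and recovery metrics;
#' percentages are printed to 2 decimals.
#'
#' @param summary Summary list from [run_pipeline()].
#' @param path Optional output file; when `NULL` the text is returned.
#' @return Character vector of report lines, invisibly when written.
#' @export
write_report <- function(summary, path = NULL) {
  fmt_counts <- function(x) {
    if (!length(x)) return("  (none)")
    sprintf("  %-24s %d", names(x), unlist(x))
  }
  lines <- c("== pipeline report ==",
             sprintf("genes: %d, samples: %d", summary$n_genes, summary$n_samples),
             "",
             "-- three-cell-type Venn (up-regulated genes) --")
  if (length(summary$venn)) {
    for (cb in names(summary$venn)) {
      lines <- c(lines, sprintf("%s:", cb), fmt_counts(summary$venn[[cb]]))
    }
  } else lines <- c(lines, "  (none)")
  lines <- c(lines, "",
             sprintf("SI-flagged records: %d of %d",
                     summary$si_flagged %||% 0L, summary$si_records %||% 0L),
             "",
             "-- promoter site Venn --", fmt_counts(summary$promoter_venn),
             "",
             "-- binding modes --")
  for (cb in names(summary$mode_counts)) {
    lines <- c(lines, sprintf("%s:", cb), fmt_counts(summary$mode_counts[[cb]]))
  }
  if (!is.null(summary$mode_overlap_pct_sum)) {
    lines <- c(lines, "", "-- mode overlap (sum method, %) --",
               sprintf("  %-24s %.2f", names(summary$mode_overlap_pct_sum),
                       unlist(summary$mode_overlap_pct_sum)))
  }
  for (which in c("alpha", "gamma")) {
    fx <- si_fixture_check(which)
    lines <- c(lines, sprintf(
      "top-30 %s fixture: %d/%d SI-flagged, %s reference flags",
      which, fx$n_flagged, fx$n_genes,
      if (fx$agrees) "matches" else "DISAGREES with"))
  }
  if (!is.null(summary$recovery)) {
    r <- summary$recovery
    lines <- c(lines, "", "-- recovery vs planted truth --",
               sprintf("  mode accuracy:   %.2f%% (%d motif-bearing genes)",
                       r$mode_accuracy_pct, r$n_motif_genes),
               sprintf("  SI sensitivity:  %.2f%%", r$si_sensitivity_pct),
               sprintf("  SI specificity:  %.2f%%", r$si_specificity_pct))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Packaged top-30 fold-change fixtures
#'
#' Curated replicate-mean fold-change triples (IFN, LPS, combined) for the
#' thirty most strongly commonly up-regulated VSMC genes under IFNa+LPS
#' (`"alpha"`) or IFNg+LPS (`"gamma"`), with annotated promoter site dots
#' and reference SI flags.
#'
#' @param which `"alpha"` or `"gamma"`.
#' @return data.frame: gene_id, fc_ifn, fc_lps, fc_combo, gas, isre,
#'   nfkb, si.
#' @export
si_fixture <- function(which = c("alpha", "gamma")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   sprintf("si_top30_%s_lps.tsv",
                           c(alpha = "ifna", gamma = "ifng")[[which]]),
                   package = "sicobind")
  utils::read.delim(f, stringsAsFactors = FALSE)
}

#' Check the SI statistic against a packaged fixture
#'
#' Applies [si_flags()] to the fixture's fold-change triples and compares
#' the computed flags with the reference flags.
#'
#' @param which `"alpha"` or `"gamma"`.
#' @return list(n_genes, n_flagged, agrees, mismatches, table).
#' @export
si_fixture_check <- function(which = c("alpha", "gamma")) {
  tab <- si_fixture(which)
  out <- si_flags(tab)
  mism <- tab$gene_id[out$si_flag != (tab$si == 1)]
  list(n_genes = nrow(tab), n_flagged = sum(out$si_flag),
       agrees = length(mism) == 0L, mismatches = mism,
       table = cbind(tab, si_flag = out$si_flag))
}
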