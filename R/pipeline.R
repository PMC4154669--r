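# End-to-end orchestration: one configuration drives simulate -> call ->
# difftest -> background -> overlap -> profile -> correlate -> report, with
# deterministic seeding, per-stage logging of record counts, and a
# machine-readable output bundle. Rerunning with the same configuration and
# seed produces byte-identical outputs.

#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the analysis
#' conventions: 200 bp read extension, 500/50 bp scan windows at a 10-read
#' threshold, p < 0.01 TSTR calling on 2 kb expression windows, 1 kb
#' feature windows with 1 kb CAGE extension, 100 background iterations at
#' thresholds 1 and 10 over 1 kb windows, 25 bp profile bins over 10 kb
#' with 5th-95th trimming and loess span 0.1, +/- 25 kb heatmaps, 20-gene
#' correlation bins over 5 nearest-gene ranks.
#'
#' @param sim A [sim_config()] for the simulate stage, or `NULL` when
#'   `input_dir` points at an existing fixture bundle.
#' @param input_dir Directory holding a bundle written by
#'   [write_fixture_bundle()] (used when `sim` is `NULL`).
#' @param stages Character vector of enabled stages, a subset of
#'   `c("simulate", "call", "background", "overlap", "profile",
#'   "correlate", "report")`. Stages whose prerequisites are disabled are
#'   skipped with a log notice.
#' @param extension,window_scan,step,min_reads Scan parameters.
#' @param alpha,expr_window Differential-test parameters.
#' @param feature_window,cage_extend Feature-overlap windows (bp).
#' @param bg_iterations,bg_thresholds,bg_window Background calibration.
#' @param chip_bin,chip_strategy,chip_min_background ChIP classification
#'   background bin width, relative-coverage strategy, and minimum
#'   background size.
#' @param profile_flank,profile_bin,trim,loess_span Metaprofile settings.
#' @param heatmap_flank,heatmap_bin Heatmap settings.
#' @param k_nearest,gene_bin Neighbor-correlation settings.
#' @param n_controls Number of random control regions for overlap
#'   enrichment (defaults to the number of TSTRs).
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            stages = c("simulate", "call", "background",
                                       "overlap", "profile", "correlate",
                                       "report"),
                            extension = 200, window_scan = 500, step = 50,
                            min_reads = 10, alpha = 0.01,
                            expr_window = 2000, feature_window = 1000,
                            cage_extend = 1000, bg_iterations = 100,
                            bg_thresholds = c(1, 10), bg_window = 1000,
                            chip_bin = 1000,
                            chip_strategy = "input_subtracted",
                            chip_min_background = 1e6,
                            profile_flank = 5000, profile_bin = 25,
                            trim = c(0.05, 0.95), loess_span = 0.1,
                            heatmap_flank = 25000, heatmap_bin = 25,
                            k_nearest = 5, gene_bin = 20,
                            n_controls = NULL, seed = 1) {
  cfg <- as.list(environment())
  known <- c("simulate", "call", "background", "overlap", "profile",
             "correlate", "report")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  if (is.null(sim) && is.null(input_dir))
    stop("either a sim config or an input_dir is required")
  structure(cfg, class = "pipeline_config")
}

#' @noRd
config_echo <- function(config) {
  flat <- lapply(config, function(v) {
    if (inherits(v, "sim_config"))
      paste0("sim_config(seed=", v$seed, ")")
    else paste(format(v), collapse = ",")
  })
  sprintf("%s = %s", names(flat), unlist(flat))
}

#' @noRd
stage_log <- function(fmt, ...) message(sprintf(paste0("[ernascan] ", fmt), ...))

#' Load a fixture bundle written by [write_fixture_bundle()]
#' @param dir Bundle directory.
#' @return List shaped like an `erna_sim` (no config).
#' @export
read_fixture_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  manifest <- read_manifest(p("manifest.txt"))
  tissues <- strsplit(manifest[["tissues"]], ",", fixed = TRUE)[[1]]
  genome <- read_tsv(p("genome.tsv"))
  rrna <- read_bed(p("rrna.bed"))
  readsets <- lapply(stats::setNames(tissues, tissues), function(t)
    read_set(read_bed(p(sprintf("reads_%s.bed", t)), unique_only = TRUE),
             rrna = rrna, tissue = t))
  enh <- read_bed(p("enhancers.bed"))
  if (nrow(enh)) {
    parts <- strsplit(enh$name, "|", fixed = TRUE)
    enh$tissue <- vapply(parts, function(x) x[length(x)], "")
    enh$name <- vapply(parts, `[[`, "", 1)
  } else enh$tissue <- character(0)
  list(genome = genome,
       annotation = structure(list(genes = read_refflat(p("genes.refflat")),
                                   rrna = rrna,
                                   exclusions = read_bed(p("exclusions.bed"))),
                              class = "annotation_set"),
       readsets = readsets,
       truth = if (file.exists(p("truth.tsv"))) read_tsv(p("truth.tsv")),
       tracks = structure(list(chip = list(p300 = read_bedgraph(p("p300.bedgraph")),
                                           k27ac = read_bedgraph(p("k27ac.bedgraph")),
                                           input = read_bedgraph(p("input.bedgraph"))),
                               phastcons = read_bed(p("phastcons.bed")),
                               cage = read_bed(p("cage.bed")),
                               enhancers = enh),
                          class = "feature_tracks"),
       tissues = tissues)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on simulated or loaded inputs and
#' (when `outdir` is given and the report stage is enabled) writes the
#' output bundle: the TSTR table, the enhancer volcano table, the
#' background threshold table, per-class summaries, metaprofile and
#' heatmap matrices, the neighbor-correlation table and a plain-text
#' report echoing the configuration.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory, or `NULL` for no files.
#' @return Object of class `erna_pipeline` with the per-stage results.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  on <- function(stage) stage %in% config$stages
  res <- list(config = config)

  if (on("simulate") && !is.null(config$sim)) {
    stage_log("simulate: seed %d", config$sim$seed)
    bundle <- simulate_bundle(config$sim)
    bundle$tissues <- config$sim$tissues
  } else {
    if (is.null(config$input_dir))
      stop("stage 'simulate' disabled and no input_dir given")
    stage_log("load: %s", config$input_dir)
    bundle <- read_fixture_bundle(config$input_dir)
  }
  res$bundle <- bundle
  tissues <- bundle$tissues
  rs_a <- bundle$readsets[[tissues[1]]]
  rs_b <- bundle$readsets[[tissues[2]]]
  stage_log("inputs: %s=%d reads (N=%d), %s=%d reads (N=%d)",
            tissues[1], nrow(rs_a$reads), rs_a$library_size,
            tissues[2], nrow(rs_b$reads), rs_b$library_size)

  if (!on("call")) {
    stage_log("stage 'call' disabled; downstream stages skipped")
    return(finish_pipeline(res, outdir))
  }
  fit <- tstr_discover(rs_a, rs_b, bundle$genome,
                       bundle$annotation$exclusions,
                       extension = config$extension,
                       window_scan = config$window_scan, step = config$step,
                       min_reads = config$min_reads,
                       expr_window = config$expr_window,
                       alpha = config$alpha)
  res$fit <- fit
  stage_log("call: %d candidate regions; TSTRs: %s", nrow(fit$table),
            paste(sprintf("%s=%d", tissues,
                          vapply(tissues, function(t)
                            sum(fit$table$tissue == t), 0L)),
                  collapse = ", "))
  ext_a <- extend_reads(rs_a, config$extension, bundle$genome)
  ext_b <- extend_reads(rs_b, config$extension, bundle$genome)

  enh <- bundle$tracks$enhancers
  if (nrow(enh)) {
    mids <- floor((enh$start + enh$end) / 2)
    ewin <- center_windows(enh$chrom, mids, config$expr_window,
                           bundle$genome)
    e_a <- count_reads_in_windows(ext_a, ewin)
    e_b <- count_reads_in_windows(ext_b, ewin)
    res$volcano <- cbind(enh[, c("chrom", "start", "end", "name", "tissue")],
                         n_a = e_a, n_b = e_b,
                         enhancer_fold_change(e_a, e_b, rs_a$library_size,
                                              rs_b$library_size))
    res$concordance <- concordance_fraction(enh$tissue, e_a, e_b, tissues)
    stage_log("enhancer catalog: %d entries, concordance %.0f%%",
              nrow(enh), 100 * res$concordance$overall)
  }

  if (on("background") && nrow(enh)) {
    model <- background_iterate(ext_a, sizes = enh$end - enh$start,
                                exclusions = bundle$annotation$exclusions,
                                genome = bundle$genome,
                                thresholds = config$bg_thresholds,
                                iterations = config$bg_iterations,
                                window = config$bg_window,
                                seed = config$seed + 1000L)
    res$background <- model
    res$threshold_table <- threshold_report(enh, ext_a, model,
                                            bundle$genome)
    stage_log("background: %d iterations over %d control regions",
              model$iterations, nrow(enh))
  } else if (on("background")) {
    stage_log("background skipped: empty enhancer catalog")
  }

  tab <- fit$table
  if (on("overlap") && nrow(tab)) {
    cons <- conservation_score(tab, bundle$tracks$phastcons,
                               window = config$feature_window,
                               genome = bundle$genome)
    tab$conservation <- cons$score
    tab$conserved <- cons$conserved
    tab$has_cage <- cage_overlap(tab, bundle$tracks$cage,
                                 window = config$feature_window,
                                 extend = config$cage_extend,
                                 genome = bundle$genome)
    ctrl <- random_control_regions(
      if (is.null(config$n_controls)) nrow(tab) else config$n_controls,
      sizes = config$feature_window, exclusions = bundle$annotation$exclusions,
      genome = bundle$genome, seed = config$seed + 2000L)
    ctrl_cons <- conservation_score(ctrl, bundle$tracks$phastcons,
                                    window = config$feature_window,
                                    genome = bundle$genome)
    ctrl_cage <- cage_overlap(ctrl, bundle$tracks$cage,
                              window = config$feature_window,
                              extend = config$cage_extend,
                              genome = bundle$genome)
    res$conservation_test <- overlap_enrichment_test(tab$conserved,
                                                     ctrl_cons$conserved)
    res$cage_test <- overlap_enrichment_test(tab$has_cage, ctrl_cage)
    bg_region <- annotation_free_space(bundle$genome, tab,
                                       bundle$annotation$exclusions)
    cls <- chip_enrichment_classify(tab, bundle$tracks$chip[c("p300", "k27ac")],
                                    bundle$tracks$chip$input, bg_region,
                                    window = config$feature_window,
                                    bin = config$chip_bin,
                                    strategy = config$chip_strategy,
                                    min_background = config$chip_min_background)
    tab <- cbind(tab, cls)
    tab$tss_distance <- distance_to_nearest_tss(tab,
                                                bundle$annotation$genes)
    res$class_summary <- class_summaries(tab)
    stage_log("overlap: conserved %.0f%% (controls %.0f%%, p=%.3g); CAGE %.0f%% (controls %.0f%%, p=%.3g)",
              100 * res$conservation_test$fraction_tstr,
              100 * res$conservation_test$fraction_control,
              res$conservation_test$p,
              100 * res$cage_test$fraction_tstr,
              100 * res$cage_test$fraction_control, res$cage_test$p)
  } else if (on("overlap")) {
    stage_log("overlap skipped: no candidate regions")
  }
  res$table <- tab

  if (on("profile") && nrow(tab)) {
    marked <- if ("class" %in% names(tab))
      tab[tab$class != "none", , drop = FALSE] else tab
    if (!on("overlap"))
      stage_log("profile: stage 'overlap' disabled, anchoring on all regions")
    anchors <- if (nrow(marked) > 0) marked else tab
    prof <- metaprofile(anchors, ext_a, bundle$genome,
                        flank = config$profile_flank,
                        bin = config$profile_bin, trim = config$trim)
    res$profile <- prof
    res$profile_smoothed <- loess_smooth(prof, span = config$loess_span)
    if ("class" %in% names(tab)) {
      res$heatmaps <- lapply(bundle$tracks$chip[c("p300", "k27ac")],
                             function(track)
                               heatmap_matrix(tab, track,
                                              bundle$tracks$chip$input,
                                              bundle$genome,
                                              flank = config$heatmap_flank,
                                              bin = config$heatmap_bin))
    } else {
      stage_log("heatmaps skipped: no enrichment classes (stage 'overlap' disabled)")
    }
    stage_log("profile: %d anchors", prof$n_anchors)
  }

  if (on("correlate") && nrow(tab)) {
    called <- tab[tab$tissue != "none", , drop = FALSE]
    if (nrow(called) >= 2 * config$gene_bin) {
      gx <- gene_expression(bundle$annotation$genes, ext_a, ext_b)
      res$correlation <- neighbor_correlation(called, gx, tissues,
                                              k_max = config$k_nearest,
                                              bin_size = config$gene_bin,
                                              seed = config$seed + 3000L)
      stage_log("correlate: rank-1 R = %.3f over %d TSTRs",
                res$correlation$r[1], nrow(called))
    } else {
      stage_log("correlate skipped: only %d called TSTRs (< %d)",
                nrow(called), 2 * config$gene_bin)
    }
  }

  finish_pipeline(res, outdir)
}

#' Background sequence: genome minus exclusions and candidate windows
#' @noRd
annotation_free_space <- function(genome, regions, exclusions) {
  len <- chrom_lengths(genome)
  occupied <- rbind(exclusions[, c("chrom", "start", "end")],
                    center_windows(regions$chrom, region_centers(regions),
                                   3000, genome)[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(as_granges(
    genomic_intervals(occupied$chrom, occupied$start, occupied$end),
    genome))
  free <- GenomicRanges::gaps(gr)
  free <- free[GenomicRanges::strand(free) == "*"]
  genomic_intervals(as.character(GenomicRanges::seqnames(free)),
                    GenomicRanges::start(free) - 1,
                    GenomicRanges::end(free))
}

#' @noRd
finish_pipeline <- function(res, outdir) {
  out <- structure(res, class = "erna_pipeline")
  if (!is.null(outdir) && "report" %in% res$config$stages)
    write_pipeline_report(out, outdir)
  out
}

#' Write the pipeline output bundle
#'
#' Emits machine-readable TSVs for every computed product plus a
#' `report.txt` summary whose header echoes the configuration verbatim.
#' Deterministic: identical results give byte-identical files.
#'
#' @param x An `erna_pipeline`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_report <- function(x, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  tissues <- x$bundle$tissues
  if (!is.null(x$table) && nrow(x$table)) {
    tab <- x$table
    tab$peak_center <- as.integer(tab$peak_center)
    num <- vapply(tab, is.double, TRUE)
    tab[num] <- lapply(tab[num], function(v) signif(v, 8))
    write_tsv(tab, p("tstr_table.tsv"))
  }
  if (!is.null(x$volcano)) {
    v <- x$volcano
    v[vapply(v, is.double, TRUE)] <-
      lapply(v[vapply(v, is.double, TRUE)], function(col) signif(col, 8))
    write_tsv(v, p("volcano.tsv"))
  }
  if (!is.null(x$threshold_table))
    write_tsv(within(x$threshold_table, {
      pct_enhancers <- signif(pct_enhancers, 8)
      pct_controls <- signif(pct_controls, 8)
      fold_ratio <- signif(fold_ratio, 8)
      p <- signif(p, 8)
    }), p("background_table.tsv"))
  if (!is.null(x$class_summary))
    write_tsv(within(x$class_summary$summary, {
      mean_rpkm <- signif(mean_rpkm, 8)
      mean_si <- signif(mean_si, 8)
      conserved_fraction <- signif(conserved_fraction, 8)
      median_di <- signif(median_di, 8)
    }), p("class_summary.tsv"))
  if (!is.null(x$profile)) {
    prof <- data.frame(position = x$profile$position,
                       sense = signif(x$profile$sense, 8),
                       antisense = signif(x$profile$antisense, 8),
                       combined = signif(x$profile$combined, 8),
                       smoothed = signif(x$profile_smoothed, 8))
    write_tsv(prof, p("profile.tsv"))
  }
  if (!is.null(x$heatmaps)) {
    for (mark in names(x$heatmaps)) {
      hm <- x$heatmaps[[mark]]
      write_tsv(hm$row_index, p(sprintf("heatmap_%s_rows.tsv", mark)))
      utils::write.table(signif(hm$matrix, 6),
                         p(sprintf("heatmap_%s.tsv", mark)), sep = "\t",
                         quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  if (!is.null(x$correlation))
    write_tsv(within(x$correlation, r <- signif(r, 8)),
              p("correlation.tsv"))

  lines <- c("# ernascan pipeline report", "# configuration:",
             paste0("#   ", config_echo(x$config)), "")
  if (!is.null(x$table)) {
    for (t in tissues)
      lines <- c(lines, sprintf("tstr_count_%s\t%d", t,
                                sum(x$table$tissue == t)))
    lines <- c(lines, sprintf("regions_tested\t%d", nrow(x$table)))
  }
  if (!is.null(x$concordance)) {
    lines <- c(lines, sprintf("concordance_overall\t%.6f",
                              x$concordance$overall),
               sprintf("concordance_%s\t%.6f", tissues,
                       x$concordance$by_tissue))
  }
  if (!is.null(x$conservation_test))
    lines <- c(lines, sprintf("conservation_fraction\t%.6f",
                              x$conservation_test$fraction_tstr),
               sprintf("conservation_p\t%.6g", x$conservation_test$p))
  if (!is.null(x$cage_test))
    lines <- c(lines, sprintf("cage_fraction\t%.6f",
                              x$cage_test$fraction_tstr),
               sprintf("cage_p\t%.6g", x$cage_test$p))
  if (!is.null(x$correlation))
    lines <- c(lines, sprintf("correlation_rank%s\t%.6f",
                              x$correlation$rank, x$correlation$r))
  writeLines(lines, p("report.txt"))
  invisible(outdir)
}

#' @export
print.erna_pipeline <- function(x, ...) {
  cat("ernascan pipeline result\n")
  if (!is.null(x$fit)) print(x$fit)
  if (!is.null(x$concordance))
    cat(sprintf("  enhancer concordance: %.0f%%\n",
                100 * x$concordance$overall))
  if (!is.null(x$conservation_test))
    cat(sprintf("  conservation: %.0f%% of TSTRs vs %.0f%% of controls (p = %.3g)\n",
                100 * x$conservation_test$fraction_tstr,
                100 * x$conservation_test$fraction_control,
                x$conservation_test$p))
  if (!is.null(x$correlation))
    cat(sprintf("  neighbor correlation (rank 1): R = %.3f\n",
                x$correlation$r[1]))
  invisible(x)
}

#' @export
summary.erna_pipeline <- function(object, ...) {
  print(object, ...)
}
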