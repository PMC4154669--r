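# Synthetic two-tissue RNA-seq world with planted intergenic transcription.
#
# The generator emulates what the discovery pipeline consumes: strand-specific
# uniquely mapped 50 bp reads for two tissues over a small genome, a gene
# annotation (refFlat-like) providing the pre-mRNA background and the
# intergenic exclusion set, rRNA loci (excluded from library size), and the
# enhancer-associated feature tracks (p300/H3K27ac ChIP coverage + input,
# phastCons elements, CAGE peaks, validated-enhancer catalog). Every planted
# locus is recorded in a truth table for parameter-recovery tests.

#' Simulation configuration
#'
#' Defaults describe the stated synthetic world: a 2 x 1 Mb genome, 100
#' tissue-specific planted loci with a 5-fold expected-count difference
#' (150 vs 30 reads) and 100 non-specific loci (60/60), 50 bp reads,
#' negative binomial count noise with dispersion 0.1 (the study pooled one
#' sample per tissue, so overdispersion is a free choice; Poisson is
#' available for exactness tests), and balanced bidirectional transcription
#' (sense fraction 0.5).
#'
#' @param chromosomes Named numeric vector of chromosome lengths (bp).
#' @param tissues Two tissue labels.
#' @param depth Relative sequencing-depth factor per tissue (length 2);
#'   expected read counts scale linearly with it, 0 gives an empty library.
#' @param n_genes Number of background genes.
#' @param gene_span Range of gene span lengths (bp).
#' @param exons_per_gene Range of exon counts per gene.
#' @param gene_reads Mean exonic read count per gene per tissue.
#' @param intron_rate Intronic read count as a fraction of the exonic count.
#' @param n_est Number of additional mRNA/EST-like exclusion intervals.
#' @param rrna_loci Number of rRNA loci.
#' @param rrna_width Width of each rRNA locus (bp).
#' @param rrna_reads Mean read count per rRNA locus per tissue.
#' @param background_rate Intergenic background read rate (reads per bp).
#' @param n_specific,n_nonspecific,n_genic_decoys Planted locus counts:
#'   tissue-specific (split evenly between tissues), non-specific
#'   intergenic, and genic decoys (inside gene bodies, must be removed by
#'   the intergenic filter).
#' @param locus_width Width of planted loci (bp).
#' @param locus_gap Minimum gap between planted loci and to annotation (bp).
#' @param mean_active,mean_inactive Expected read counts of a specific locus
#'   in its active / other tissue (default 150 vs 30: 5-fold).
#' @param mean_nonspecific Expected read count of a non-specific locus.
#' @param sense_fraction Probability a locus read falls on the + strand.
#' @param p_p300,p_k27ac,p_conserved,p_cage,p_enhancer Per-locus feature
#'   flag probabilities for tissue-specific loci.
#' @param noise Count noise model, `"poisson"` (default; sampling noise of
#'   a single pooled library, matching the binomial model behind the
#'   two-proportion z-test) or `"nb"` (adds locus-level biological
#'   variability; under it, equal-mean loci are no longer truly
#'   non-specific).
#' @param dispersion Negative binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param read_length Read length (bp), pre-extension.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(chromosomes = c(chr1 = 1e6, chr2 = 1e6),
                       tissues = c("A", "B"),
                       depth = c(1, 1),
                       n_genes = 20,
                       gene_span = c(5000, 15000),
                       exons_per_gene = c(3, 8),
                       gene_reads = 200,
                       intron_rate = 0.1,
                       n_est = 10,
                       rrna_loci = 2,
                       rrna_width = 5000,
                       rrna_reads = 3000,
                       background_rate = 5e-4,
                       n_specific = 100,
                       n_nonspecific = 100,
                       n_genic_decoys = 20,
                       locus_width = 1000,
                       locus_gap = 3000,
                       mean_active = 150,
                       mean_inactive = 30,
                       mean_nonspecific = 60,
                       sense_fraction = 0.5,
                       p_p300 = 0.4,
                       p_k27ac = 0.4,
                       p_conserved = 0.7,
                       p_cage = 0.5,
                       p_enhancer = 0.15,
                       noise = c("poisson", "nb"),
                       dispersion = 0.1,
                       read_length = 50,
                       seed = 1) {
  noise <- match.arg(noise)
  cfg <- as.list(environment())
  if (length(cfg$chromosomes) == 0)
    stop("config error: at least one chromosome is required")
  if (any(cfg$chromosomes <= 0))
    stop("config error: non-positive chromosome length")
  if (is.null(names(cfg$chromosomes)) || anyDuplicated(names(cfg$chromosomes)))
    stop("config error: chromosome names must be unique and non-empty")
  if (length(cfg$tissues) != 2 || anyDuplicated(cfg$tissues))
    stop("config error: exactly two distinct tissues are required")
  if (length(cfg$depth) != 2 || any(cfg$depth < 0))
    stop("config error: depth must be two non-negative factors")
  if (cfg$dispersion <= 0) stop("config error: dispersion must be > 0")
  if (cfg$sense_fraction < 0 || cfg$sense_fraction > 1)
    stop("config error: sense_fraction must lie in [0, 1]")
  if (any(c(cfg$mean_active, cfg$mean_inactive, cfg$mean_nonspecific) < 0))
    stop("config error: locus means must be >= 0")
  names(cfg$depth) <- cfg$tissues
  structure(cfg, class = "sim_config")
}

#' Evaluate code under a fixed seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
draw_counts <- function(n, mu, config) {
  mu <- rep_len(mu, n)
  out <- integer(n)
  pos <- mu > 0
  if (any(pos)) {
    out[pos] <- if (config$noise == "poisson") {
      stats::rpois(sum(pos), mu[pos])
    } else {
      stats::rnbinom(sum(pos), size = 1 / config$dispersion, mu = mu[pos])
    }
  }
  out
}

#' Build the genome model
#' @param config A [sim_config()].
#' @return Data frame with columns `chrom`, `length`.
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  data.frame(chrom = names(config$chromosomes),
             length = unname(config$chromosomes),
             stringsAsFactors = FALSE)
}

#' @noRd
sample_chrom <- function(genome) {
  sample(genome$chrom, 1, prob = genome$length)
}

# Sequential random placement with a retry budget. `occupied` is an interval
# data frame; candidates must keep `gap` bp clear of every occupied interval.
# Overlap checks are plain vectorized comparisons per chromosome (hot path).
#' @noRd
place_intervals <- function(n, widths, genome, occupied, gap = 0,
                            retries_per = 200, what = "interval") {
  widths <- rep_len(widths, n)
  out_chrom <- character(n); out_start <- numeric(n)
  len <- chrom_lengths(genome)
  occ <- lapply(stats::setNames(genome$chrom, genome$chrom), function(ch) {
    sel <- occupied$chrom == ch
    list(start = occupied$start[sel], end = occupied$end[sel])
  })
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(retries_per)) {
      chrom <- sample_chrom(genome)
      w <- widths[i]
      if (len[[chrom]] <= w) next
      start <- floor(stats::runif(1, 0, len[[chrom]] - w))
      o <- occ[[chrom]]
      if (!any(o$start < start + w + gap & o$end > start - gap)) {
        out_chrom[i] <- chrom; out_start[i] <- start
        occ[[chrom]]$start <- c(o$start, start)
        occ[[chrom]]$end <- c(o$end, start + w)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("generation error: could not place %s %d without overlap (density too high)",
                   what, i))
  }
  data.frame(chrom = out_chrom, start = out_start, end = out_start + widths,
             stringsAsFactors = FALSE)
}

#' Simulate the gene/rRNA/EST annotation
#'
#' Places non-overlapping genes with exon structure, rRNA loci, and
#' additional mRNA/EST-like intervals. The exclusion set (gene spans +
#' ESTs + rRNA) is what the intergenic filter removes against, mirroring
#' filtering of transcribed regions that overlap known genes, mRNAs or
#' ESTs.
#'
#' @param genome Genome model from [build_genome()].
#' @param config A [sim_config()].
#' @return Object of class `annotation_set`: list with `genes` (refFlat-like
#'   data frame), `rrna`, `est`, and `exclusions` interval data frames.
#' @export
build_annotation <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    spans <- place_intervals(
      config$n_genes,
      widths = floor(stats::runif(config$n_genes, config$gene_span[1],
                                  config$gene_span[2])),
      genome = genome, occupied = empty_intervals(), gap = 500,
      what = "gene")
    genes <- lapply(seq_len(nrow(spans)), function(i) {
      span <- spans[i, ]
      w <- span$end - span$start
      k <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1)
      # split the span into 2k-1 alternating exon/intron blocks
      cuts <- sort(sample(seq_len(w - 1), 2 * k - 2))
      bounds <- c(0, cuts, w) + span$start
      starts <- bounds[seq(1, 2 * k - 1, by = 2)]
      ends <- bounds[seq(2, 2 * k, by = 2)]
      data.frame(gene = sprintf("gene%03d", i),
                 name = sprintf("tx%03d", i),
                 chrom = span$chrom, strand = sample(c("+", "-"), 1),
                 tx_start = span$start, tx_end = span$end,
                 cds_start = span$start, cds_end = span$end,
                 exon_count = k, stringsAsFactors = FALSE,
                 exon_starts = I(list(starts)), exon_ends = I(list(ends)))
    })
    genes <- do.call(rbind, genes)
    occupied <- genomic_intervals(genes$chrom, genes$tx_start, genes$tx_end)
    rrna <- place_intervals(config$rrna_loci, config$rrna_width, genome,
                            occupied, gap = 500, what = "rRNA locus")
    rrna <- genomic_intervals(rrna$chrom, rrna$start, rrna$end,
                              name = sprintf("rRNA%02d", seq_len(nrow(rrna))))
    occupied <- rbind(occupied, rrna)
    est <- place_intervals(config$n_est,
                           widths = floor(stats::runif(config$n_est, 500, 3000)),
                           genome = genome, occupied = occupied, gap = 500,
                           what = "EST")
    est <- genomic_intervals(est$chrom, est$start, est$end,
                             name = sprintf("est%03d", seq_len(nrow(est))))
    gene_iv <- genomic_intervals(genes$chrom, genes$tx_start, genes$tx_end,
                                 name = genes$gene, strand = genes$strand)
    exclusions <- rbind(gene_iv, est, rrna)
    structure(list(genes = genes, rrna = rrna, est = est,
                   exclusions = exclusions),
              class = "annotation_set")
  })
}

#' Plant intergenic (and optional genic decoy) transcription loci
#'
#' Tissue-specific loci (split evenly between the two tissues) get
#' `mean_active` expected reads in their active tissue and `mean_inactive`
#' in the other; non-specific loci get `mean_nonspecific` in both. Feature
#' flags (p300, H3K27ac, conservation, CAGE, known enhancer) are drawn per
#' specific locus; non-specific loci carry background feature rates.
#' Intergenic loci keep `locus_gap` bp clear of the annotation and of each
#' other, so the intergenic filter must retain all of them.
#'
#' @param genome Genome model.
#' @param annotation An `annotation_set`.
#' @param config A [sim_config()].
#' @return Truth table data frame (one row per planted locus).
#' @export
plant_loci <- function(genome, annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    n_int <- config$n_specific + config$n_nonspecific
    placed <- place_intervals(n_int, config$locus_width, genome,
                              occupied = annotation$exclusions,
                              gap = config$locus_gap, what = "planted locus")
    tissues <- config$tissues
    active <- c(rep(tissues, length.out = config$n_specific),
                rep("none", config$n_nonspecific))
    mean_a <- ifelse(active == tissues[1], config$mean_active,
                     ifelse(active == tissues[2], config$mean_inactive,
                            config$mean_nonspecific))
    mean_b <- ifelse(active == tissues[2], config$mean_active,
                     ifelse(active == tissues[1], config$mean_inactive,
                            config$mean_nonspecific))
    specific <- active != "none"
    flag <- function(p) specific & stats::runif(n_int) < p
    loci <- data.frame(
      locus_id = sprintf("locus%03d", seq_len(n_int)),
      chrom = placed$chrom, start = placed$start, end = placed$end,
      mean_reads_A = mean_a, mean_reads_B = mean_b,
      sense_fraction = config$sense_fraction,
      has_p300 = flag(config$p_p300),
      has_k27ac = flag(config$p_k27ac),
      conserved = flag(config$p_conserved),
      has_cage = flag(config$p_cage),
      is_known_enhancer = flag(config$p_enhancer),
      active_tissue = active, genic = FALSE,
      stringsAsFactors = FALSE)
    if (config$n_genic_decoys > 0) {
      g <- annotation$genes
      gi <- sample(nrow(g), config$n_genic_decoys, replace = TRUE)
      w <- pmin(config$locus_width, g$tx_end[gi] - g$tx_start[gi])
      off <- floor(stats::runif(config$n_genic_decoys) *
                     (g$tx_end[gi] - g$tx_start[gi] - w + 1))
      decoys <- data.frame(
        locus_id = sprintf("decoy%03d", seq_len(config$n_genic_decoys)),
        chrom = g$chrom[gi], start = g$tx_start[gi] + off,
        end = g$tx_start[gi] + off + w,
        mean_reads_A = config$mean_nonspecific,
        mean_reads_B = config$mean_nonspecific,
        sense_fraction = config$sense_fraction,
        has_p300 = FALSE, has_k27ac = FALSE, conserved = FALSE,
        has_cage = FALSE, is_known_enhancer = FALSE,
        active_tissue = "none", genic = TRUE, stringsAsFactors = FALSE)
      loci <- rbind(loci, decoys)
    }
    # names for tissue-mean columns follow configured tissue labels
    names(loci)[names(loci) == "mean_reads_A"] <-
      paste0("mean_reads_", tissues[1])
    names(loci)[names(loci) == "mean_reads_B"] <-
      paste0("mean_reads_", tissues[2])
    loci
  })
}

#' @noRd
uniform_reads <- function(n, chrom, start, end, read_length, sense_fraction,
                          prefix) {
  if (n == 0) return(empty_intervals())
  lo <- start
  hi <- max(start, end - read_length)
  s <- floor(stats::runif(n, lo, hi + 1))
  genomic_intervals(chrom = rep(chrom, n), start = s, end = s + read_length,
                    name = sprintf("%s_%d", prefix, seq_len(n)), score = 1,
                    strand = ifelse(stats::runif(n) < sense_fraction, "+", "-"))
}

#' Simulate strand-specific read sets for both tissues
#'
#' Per-locus read counts are drawn from the configured noise model around
#' the locus means scaled by the tissue depth factor; read strands are
#' Bernoulli(sense_fraction). Gene-derived background reads cover exons
#' and, at `intron_rate`, introns; rRNA loci receive reads that are
#' excluded from the library size; a uniform intergenic background is
#' added. All reads are 50 bp (pre-extension) and flagged unique.
#'
#' @param genome Genome model.
#' @param annotation An `annotation_set`.
#' @param loci Truth table from [plant_loci()].
#' @param config A [sim_config()].
#' @return List with `readsets` (named list of [read_set()] per tissue) and
#'   `truth` (the locus table with realized per-tissue counts appended).
#' @export
simulate_reads <- function(genome, annotation, loci, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 3L, {
    rl <- config$read_length
    truth <- loci
    readsets <- list()
    for (t in config$tissues) {
      d <- config$depth[[t]]
      parts <- list()
      if (d > 0 && nrow(loci) > 0) {
        mu <- loci[[paste0("mean_reads_", t)]] * d
        counts <- draw_counts(nrow(loci), mu, config)
        truth[[paste0("count_", t)]] <- counts
        parts <- c(parts, lapply(which(counts > 0), function(i) {
          uniform_reads(counts[i], loci$chrom[i], loci$start[i], loci$end[i],
                        rl, loci$sense_fraction[i],
                        sprintf("%s_%s", t, loci$locus_id[i]))
        }))
      } else {
        truth[[paste0("count_", t)]] <- 0L
      }
      if (d > 0) {
        g <- annotation$genes
        for (i in seq_len(nrow(g))) {
          n_ex <- draw_counts(1, config$gene_reads * d, config)
          if (n_ex > 0) {
            ex_w <- g$exon_ends[[i]] - g$exon_starts[[i]]
            which_ex <- sample.int(length(ex_w), n_ex, replace = TRUE,
                                   prob = ex_w)
            s <- floor(g$exon_starts[[i]][which_ex] +
                         stats::runif(n_ex) * pmax(1, ex_w[which_ex] - rl))
            parts <- c(parts, list(genomic_intervals(
              chrom = rep(g$chrom[i], n_ex), start = s, end = s + rl,
              name = sprintf("%s_%s_ex%d", t, g$gene[i], seq_len(n_ex)),
              score = 1, strand = g$strand[i])))
          }
          # intron blocks between consecutive exons
          in_s <- g$exon_ends[[i]][-g$exon_count[i]]
          in_e <- g$exon_starts[[i]][-1]
          in_w <- in_e - in_s
          if (length(in_w) && sum(in_w) > rl) {
            n_in <- draw_counts(1, config$gene_reads * config$intron_rate * d,
                                config)
            if (n_in > 0) {
              which_in <- sample.int(length(in_w), n_in, replace = TRUE,
                                     prob = in_w)
              s <- floor(in_s[which_in] +
                           stats::runif(n_in) * pmax(1, in_w[which_in] - rl))
              parts <- c(parts, list(genomic_intervals(
                chrom = rep(g$chrom[i], n_in), start = s, end = s + rl,
                name = sprintf("%s_%s_in%d", t, g$gene[i], seq_len(n_in)),
                score = 1, strand = g$strand[i])))
            }
          }
        }
        r <- annotation$rrna
        for (i in seq_len(nrow(r))) {
          n_r <- draw_counts(1, config$rrna_reads * d, config)
          parts <- c(parts, list(uniform_reads(
            n_r, r$chrom[i], r$start[i], r$end[i], rl, 0.5,
            sprintf("%s_%s", t, r$name[i]))))
        }
        n_bg <- stats::rpois(1, config$background_rate * sum(genome$length) * d)
        if (n_bg > 0) {
          chroms <- sample(genome$chrom, n_bg, replace = TRUE,
                           prob = genome$length)
          len <- chrom_lengths(genome)
          s <- floor(stats::runif(n_bg) * (len[chroms] - rl))
          parts <- c(parts, list(genomic_intervals(
            chrom = chroms, start = s, end = s + rl,
            name = sprintf("%s_bg_%d", t, seq_len(n_bg)), score = 1,
            strand = ifelse(stats::runif(n_bg) < 0.5, "+", "-"))))
        }
      }
      reads <- if (length(parts)) do.call(rbind, parts) else empty_intervals()
      rownames(reads) <- NULL
      readsets[[t]] <- read_set(reads, rrna = annotation$rrna, tissue = t)
    }
    list(readsets = readsets, truth = truth)
  })
}

#' Simulate enhancer-associated feature tracks
#'
#' ChIP coverage (p300, H3K27ac) is per-100 bp-bin Poisson background
#' (mean `chip_background`) plus an `chip_amplitude` boost over flagged
#' loci; the input track is pure background. phastCons elements cover the
#' centers of `conserved` loci (plus background elements kept >= 2 kb away
#' from non-conserved locus centers, so truth stays clean); CAGE peaks sit
#' at `has_cage` locus centers; known-enhancer records carry the active
#' tissue label.
#'
#' @param loci Truth table from [plant_loci()].
#' @param annotation An `annotation_set`.
#' @param genome Genome model.
#' @param config A [sim_config()].
#' @param chip_background Mean background ChIP reads per 100 bp bin.
#' @param chip_amplitude Added ChIP signal over a flagged locus.
#' @return Object of class `feature_tracks`: list with `chip` (bedGraph
#'   data frames `p300`, `k27ac`, `input`), `phastcons`, `cage`,
#'   `enhancers`.
#' @export
simulate_feature_tracks <- function(loci, annotation, genome, config,
                                    chip_background = 10,
                                    chip_amplitude = 60) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 4L, {
    bin <- 100L
    len <- chrom_lengths(genome)
    mk_track <- function(flag_col) {
      parts <- lapply(genome$chrom, function(chrom) {
        nb <- ceiling(len[[chrom]] / bin)
        v <- stats::rpois(nb, chip_background)
        if (!is.null(flag_col)) {
          sel <- loci$chrom == chrom & loci[[flag_col]]
          for (i in which(sel)) {
            b0 <- floor(loci$start[i] / bin) + 1
            b1 <- ceiling(loci$end[i] / bin)
            v[b0:b1] <- v[b0:b1] + chip_amplitude
          }
        }
        starts <- (seq_len(nb) - 1) * bin
        data.frame(chrom = chrom, start = starts,
                   end = pmin(starts + bin, len[[chrom]]), name = ".",
                   score = v, strand = ".", stringsAsFactors = FALSE)
      })
      do.call(rbind, parts)
    }
    p300 <- mk_track("has_p300")
    k27ac <- mk_track("has_k27ac")
    input <- mk_track(NULL)

    centers <- floor((loci$start + loci$end) / 2)
    planted <- function(flag, width, score = NULL) {
      idx <- which(loci[[flag]])
      if (length(idx) == 0) return(empty_intervals())
      genomic_intervals(chrom = loci$chrom[idx],
                        start = centers[idx] - floor(width / 2),
                        end = centers[idx] - floor(width / 2) + width,
                        name = loci$locus_id[idx],
                        score = if (is.null(score)) 0 else score(length(idx)))
    }
    phast <- planted("conserved", 300,
                     score = function(n) floor(stats::runif(n, 350, 600)))
    # background elements, clear of every planted locus center
    clear <- center_windows(loci$chrom, centers, 4000, genome)
    bg_ph <- place_intervals(150, floor(stats::runif(150, 100, 1000)),
                             genome, occupied = clear, gap = 0,
                             what = "phastCons element")
    bg_ph <- genomic_intervals(bg_ph$chrom, bg_ph$start, bg_ph$end,
                               name = "bg",
                               score = floor(stats::runif(nrow(bg_ph), 100, 600)))
    phast <- rbind(phast, bg_ph)
    cage <- planted("has_cage", 50)
    clear_cage <- center_windows(loci$chrom, centers, 7000, genome)
    bg_cage <- place_intervals(100, floor(stats::runif(100, 20, 200)),
                               genome, occupied = clear_cage, gap = 0,
                               what = "CAGE peak")
    cage <- rbind(cage, genomic_intervals(bg_cage$chrom, bg_cage$start,
                                          bg_cage$end, name = "bg"))
    idx <- which(loci$is_known_enhancer)
    enhancers <- genomic_intervals(loci$chrom[idx], loci$start[idx],
                                   loci$end[idx], name = loci$locus_id[idx])
    enhancers$tissue <- loci$active_tissue[idx]
    structure(list(chip = list(p300 = p300, k27ac = k27ac, input = input),
                   phastcons = phast, cage = cage, enhancers = enhancers,
                   chip_bin = bin),
              class = "feature_tracks")
  })
}

#' Generate a complete synthetic fixture bundle
#'
#' Runs genome, annotation, locus, read and feature-track generation under
#' the configured seed.
#'
#' @param config A [sim_config()].
#' @return Object of class `erna_sim`: list with `config`, `genome`,
#'   `annotation`, `loci`, `readsets`, `truth`, `tracks`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  genome <- build_genome(config)
  annotation <- build_annotation(genome, config)
  loci <- plant_loci(genome, annotation, config)
  sim <- simulate_reads(genome, annotation, loci, config)
  tracks <- simulate_feature_tracks(loci, annotation, genome, config)
  structure(list(config = config, genome = genome, annotation = annotation,
                 loci = loci, readsets = sim$readsets, truth = sim$truth,
                 tracks = tracks),
            class = "erna_sim")
}

#' @export
print.erna_sim <- function(x, ...) {
  cat(sprintf("synthetic eRNA bundle: %d chromosome(s), %d planted loci\n",
              nrow(x$genome), nrow(x$truth)))
  for (t in x$config$tissues)
    cat(sprintf("  tissue %s: %d reads, N = %d\n", t,
                nrow(x$readsets[[t]]$reads), x$readsets[[t]]$library_size))
  invisible(x)
}

#' Write a fixture bundle to disk
#'
#' Emits reads as BED6 per tissue (score 1 = uniquely mapped), the gene
#' table as refFlat, exclusion/rRNA/phastCons/CAGE/enhancer intervals as
#' BED, ChIP coverage as bedGraph, the truth table as TSV, and a key-value
#' manifest recording the seed and per-tissue library sizes. Identical
#' (config, seed) produce byte-identical bundles.
#'
#' @param sim An `erna_sim` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  for (t in sim$config$tissues)
    write_bed(sim$readsets[[t]]$reads, p(sprintf("reads_%s.bed", t)))
  write_refflat(sim$annotation$genes, p("genes.refflat"))
  write_bed(sim$annotation$exclusions, p("exclusions.bed"))
  write_bed(sim$annotation$rrna, p("rrna.bed"))
  write_bedgraph(sim$tracks$chip$p300, p("p300.bedgraph"))
  write_bedgraph(sim$tracks$chip$k27ac, p("k27ac.bedgraph"))
  write_bedgraph(sim$tracks$chip$input, p("input.bedgraph"))
  write_bed(sim$tracks$phastcons, p("phastcons.bed"))
  write_bed(sim$tracks$cage, p("cage.bed"))
  enh <- sim$tracks$enhancers
  enh$name <- paste(enh$name, enh$tissue, sep = "|")
  write_bed(enh[, c("chrom", "start", "end", "name", "score", "strand")],
            p("enhancers.bed"))
  write_tsv(sim$truth, p("truth.tsv"))
  write_tsv(sim$genome, p("genome.tsv"))
  manifest <- c(list(seed = sim$config$seed,
                     tissues = paste(sim$config$tissues, collapse = ",")),
                stats::setNames(
                  lapply(sim$config$tissues,
                         function(t) sim$readsets[[t]]$library_size),
                  paste0("library_size_", sim$config$tissues)),
                stats::setNames(
                  lapply(sim$config$tissues,
                         function(t) nrow(sim$readsets[[t]]$reads)),
                  paste0("total_reads_", sim$config$tissues)))
  write_manifest(manifest, p("manifest.txt"))
  invisible(dir)
}
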