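# Overlap of TSTRs with enhancer-associated features: phastCons
# conservation, CAGE-defined TSS candidates, p300/H3K27ac ChIP enrichment
# classification against a 95th-percentile background, Fisher's exact
# enrichment tests, and TSS-distance summaries.

#' @noRd
region_centers <- function(x) {
  if ("peak_center" %in% names(x)) x$peak_center
  else floor((x$start + x$end) / 2)
}

#' Conservation score of each region
#'
#' The score of the most highly constrained phastCons element overlapping
#' the 1 kb window around each region's peak center; regions with no
#' overlapping element get `NA` and `conserved = FALSE`. An element
#' touching a single window base counts as overlapping.
#'
#' @param tstrs Region data frame.
#' @param phastcons Interval data frame with `score` (phastCons elements).
#' @param window Window width around the peak center (default 1000).
#' @param genome Optional genome model for clipping.
#' @return Data frame with `score` (max overlapping element score or `NA`)
#'   and `conserved` flag, one row per region.
#' @export
conservation_score <- function(tstrs, phastcons, window = 1000,
                               genome = NULL) {
  win <- center_windows(tstrs$chrom, region_centers(tstrs), window, genome)
  score <- rep(NA_real_, nrow(tstrs))
  if (nrow(phastcons) > 0 && nrow(tstrs) > 0) {
    hits <- overlap_query(win, phastcons)
    if (nrow(hits)) {
      mx <- tapply(phastcons$score[hits$subject], hits$query, max)
      score[as.integer(names(mx))] <- as.numeric(mx)
    }
  }
  data.frame(score = score, conserved = !is.na(score))
}

#' CAGE TSS overlap flag per region
#'
#' CAGE peaks are reduced to their midpoints and extended 1 kb to each
#' side; a region overlaps a candidate TSS when its 1 kb center window
#' intersects any such interval.
#'
#' @param tstrs Region data frame.
#' @param cage Interval data frame of CAGE peaks (may be empty).
#' @param window Region window width (default 1000).
#' @param extend Extension each side of the CAGE midpoint (default 1000).
#' @param genome Optional genome model for clipping.
#' @return Logical vector along rows of `tstrs`.
#' @export
cage_overlap <- function(tstrs, cage, window = 1000, extend = 1000,
                         genome = NULL) {
  if (nrow(tstrs) == 0) return(logical(0))
  if (nrow(cage) == 0) return(rep(FALSE, nrow(tstrs)))
  win <- center_windows(tstrs$chrom, region_centers(tstrs), window, genome)
  mids <- floor((cage$start + cage$end) / 2)
  cage_win <- center_windows(cage$chrom, mids, 2 * extend, genome)
  overlaps_any(win, cage_win)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Sums hypergeometric probabilities of all tables (at fixed margins) whose
#' probability does not exceed that of the observed table (with the usual
#' 1 + 1e-7 relative tolerance for ties). A zero row or column margin
#' returns p = 1 with a warning.
#'
#' @param a,b First row counts.
#' @param c,d Second row counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    warning("zero margin in 2x2 table; p = 1")
    return(1)
  }
  m <- a + b
  n <- c + d
  k <- a + c
  x <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Feature-enrichment test of TSTRs against matched controls
#'
#' Builds the 2x2 table (overlapping / not, TSTRs vs controls) and applies
#' [fisher_exact_2x2()]; used for conservation and CAGE enrichment.
#'
#' @param tstr_flag Logical overlap flags for TSTRs.
#' @param control_flag Logical overlap flags for control regions.
#' @return List with `table` (2x2 matrix), `fraction_tstr`,
#'   `fraction_control`, `p`.
#' @export
overlap_enrichment_test <- function(tstr_flag, control_flag) {
  tab <- matrix(c(sum(tstr_flag), sum(!tstr_flag),
                  sum(control_flag), sum(!control_flag)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("tstr", "control"),
                                c("overlap", "no_overlap")))
  list(table = tab,
       fraction_tstr = mean(tstr_flag),
       fraction_control = mean(control_flag),
       p = fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
}

#' @noRd
tile_intervals <- function(x, bin) {
  parts <- lapply(seq_len(nrow(x)), function(i) {
    w <- x$end[i] - x$start[i]
    nb <- floor(w / bin)
    if (nb == 0) return(NULL)
    starts <- x$start[i] + (seq_len(nb) - 1) * bin
    data.frame(chrom = x$chrom[i], start = starts, end = starts + bin,
               stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) return(empty_intervals())
  out <- do.call(rbind, parts)
  genomic_intervals(out$chrom, out$start, out$end)
}

#' @noRd
depth_normalize <- function(track) {
  w <- track$end - track$start
  total <- sum(track$score * w)
  if (total <= 0) return(track)
  track$score <- track$score / (total / sum(w))
  track
}

#' Classify regions by p300/H3K27ac ChIP enrichment
#'
#' A region is enriched for a mark when its relative ChIP coverage (mean
#' depth over the 1 kb window around the peak center, depth-normalized and,
#' under the default strategy, input-subtracted) is equal to or greater
#' than the 95th percentile of background coverage, estimated over bins
#' tiling at least 1 Mb of background sequence. The combined class is one
#' of `none`, `k27ac_only`, `p300_only`, `both`.
#'
#' @param tstrs Region data frame.
#' @param chip Named list of bedGraph data frames, e.g.
#'   `list(p300 = ..., k27ac = ...)`.
#' @param input bedGraph data frame of the matched input experiment.
#' @param background_region Interval data frame of background sequence
#'   (>= `min_background` bp in total).
#' @param window Region window width (default 1000).
#' @param bin Background bin width (default 1000).
#' @param strategy `"input_subtracted"` (relative coverage = normalized
#'   ChIP - normalized input) or `"raw"` (normalized ChIP only).
#' @param min_background Minimum background size in bp (default 1e6,
#'   matching an estimate across 1 Mb of unique sequence; reduce only for
#'   small test genomes).
#' @return Data frame with one logical column `enriched_<mark>` per mark
#'   plus `class`.
#' @export
chip_enrichment_classify <- function(tstrs, chip, input, background_region,
                                     window = 1000, bin = 1000,
                                     strategy = c("input_subtracted", "raw"),
                                     min_background = 1e6) {
  strategy <- match.arg(strategy)
  if (sum(background_region$end - background_region$start) < min_background)
    stop(sprintf("background region shorter than %g bp", min_background))
  bg_bins <- tile_intervals(background_region, bin)
  win <- center_windows(tstrs$chrom, region_centers(tstrs), window)
  input_n <- depth_normalize(input)
  rel_value <- function(track, where) {
    v <- track_window_mean(depth_normalize(track), where)
    if (strategy == "input_subtracted")
      v <- v - track_window_mean(input_n, where)
    v
  }
  out <- data.frame(row.names = seq_len(max(nrow(tstrs), 0)))
  for (mark in names(chip)) {
    cutoff <- stats::quantile(rel_value(chip[[mark]], bg_bins), 0.95,
                              names = FALSE)
    out[[paste0("enriched_", mark)]] <- rel_value(chip[[mark]], win) >= cutoff
    attr(out, paste0("cutoff_", mark)) <- cutoff
  }
  if (all(c("p300", "k27ac") %in% names(chip)))
    out$class <- enrichment_class(out$enriched_p300, out$enriched_k27ac)
  out
}

#' Derive the enrichment class from per-mark flags
#' @param p300,k27ac Logical enrichment flags.
#' @return Factor with levels `none`, `k27ac_only`, `p300_only`, `both`
#'   (the heatmap row order).
#' @export
enrichment_class <- function(p300, k27ac) {
  factor(ifelse(p300 & k27ac, "both",
                ifelse(p300, "p300_only",
                       ifelse(k27ac, "k27ac_only", "none"))),
         levels = c("none", "k27ac_only", "p300_only", "both"))
}

#' Distance from each region's center to the nearest TSS
#'
#' TSS positions are strand-aware (`tx_start` for `+` genes, `tx_end` for
#' `-` genes); distance is `min |center - TSS|` over all genes.
#'
#' @param tstrs Region data frame.
#' @param genes Gene table (refFlat-like).
#' @return Numeric vector of distances in bp.
#' @export
distance_to_nearest_tss <- function(tstrs, genes) {
  if (nrow(genes) == 0) stop("no genes available for TSS distances")
  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  centers <- region_centers(tstrs)
  vapply(seq_len(nrow(tstrs)), function(i) {
    same <- genes$chrom == tstrs$chrom[i]
    if (!any(same)) return(NA_real_)
    min(abs(centers[i] - tss[same]))
  }, 0)
}

#' Per-class characterization of TSTRs
#'
#' Summarizes expression, conservation, directionality and TSS distance by
#' ChIP enrichment class, and returns cumulative directionality-index
#' curves per class. Empty classes produce `NA` rows.
#'
#' @param tab TSTR table with columns `class`, `si`, `di_a`, `di_b`,
#'   `rpkm_a`, `rpkm_b`, `conserved`, `tss_distance` (missing columns are
#'   skipped).
#' @return List with `summary` (one row per class) and `di_cdf` (named list
#'   of data frames `di`, `cum`).
#' @export
class_summaries <- function(tab) {
  stopifnot("class" %in% names(tab))
  classes <- levels(tab$class)
  di_all <- if (all(c("di_a", "di_b") %in% names(tab)))
    pmax(tab$di_a, tab$di_b) else NULL
  rows <- lapply(classes, function(cl) {
    sel <- tab$class == cl
    if (!any(sel)) {
      return(data.frame(class = cl, n = 0L, mean_rpkm = NA_real_,
                        mean_si = NA_real_, conserved_fraction = NA_real_,
                        median_di = NA_real_, median_tss_distance = NA_real_))
    }
    data.frame(
      class = cl, n = sum(sel),
      mean_rpkm = if (all(c("rpkm_a", "rpkm_b") %in% names(tab)))
        mean(pmax(tab$rpkm_a[sel], tab$rpkm_b[sel])) else NA_real_,
      mean_si = if ("si" %in% names(tab)) mean(tab$si[sel]) else NA_real_,
      conserved_fraction = if ("conserved" %in% names(tab))
        mean(tab$conserved[sel]) else NA_real_,
      median_di = if (!is.null(di_all)) stats::median(di_all[sel])
      else NA_real_,
      median_tss_distance = if ("tss_distance" %in% names(tab))
        stats::median(tab$tss_distance[sel]) else NA_real_)
  })
  di_cdf <- NULL
  if (!is.null(di_all)) {
    di_cdf <- lapply(stats::setNames(classes, classes), function(cl) {
      v <- sort(di_all[tab$class == cl])
      if (!length(v)) return(data.frame(di = numeric(0), cum = numeric(0)))
      data.frame(di = v, cum = seq_along(v) / length(v))
    })
  }
  list(summary = do.call(rbind, rows), di_cdf = di_cdf)
}
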