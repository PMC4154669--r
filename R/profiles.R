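# Strand-separated trimmed-mean eRNA metaprofiles around ChIP-defined
# anchor points, loess smoothing, and +/-25 kb z-scaled ChIP heatmap
# matrices around TSTR centers.

#' Anchor positions at maximum ChIP coverage within peaks
#'
#' For each ChIP peak, the position of maximum coverage in the given track
#' (leftmost on ties), used as the metaprofile anchor center.
#'
#' @param peaks Interval data frame of ChIP peaks.
#' @param track bedGraph data frame of ChIP coverage.
#' @return Numeric vector of 0-based anchor positions.
#' @export
anchor_centers <- function(peaks, track) {
  vapply(seq_len(nrow(peaks)), function(i) {
    sel <- track$chrom == peaks$chrom[i] & track$end > peaks$start[i] &
      track$start < peaks$end[i]
    sub <- track[sel, , drop = FALSE]
    if (nrow(sub) == 0) return(floor((peaks$start[i] + peaks$end[i]) / 2))
    best <- sub[which.max(sub$score), ]
    max(best$start, peaks$start[i])
  }, 0)
}

#' @noRd
trimmed_col_means <- function(mat, lo = 0.05, hi = 0.95) {
  apply(mat, 2, function(v) {
    q <- stats::quantile(v, c(lo, hi), names = FALSE, type = 7)
    keep <- v >= q[1] & v <= q[2]
    mean(v[keep])
  })
}

#' Strand-separated trimmed-mean coverage metaprofile
#'
#' Mean read coverage in 25 bp bins across a 10 kb window centered on each
#' anchor, averaged over anchors after discarding, per bin, values outside
#' the 5th-95th percentile of that bin's across-anchor distribution
#' (outlier-region control), and scaled per million mapped reads. Computed
#' separately for sense (+), antisense (-) and combined reads.
#'
#' @param anchors Numeric anchor center positions with a parallel `chrom`
#'   vector, or an interval data frame (centers taken from `peak_center`
#'   or midpoints).
#' @param reads A [read_set()] of extended reads.
#' @param genome Genome model.
#' @param flank Half-window in bp (default 5000: a 10 kb window).
#' @param bin Bin width in bp (default 25; 400 bins).
#' @param trim Lower/upper trim quantiles (default `c(0.05, 0.95)`).
#' @return Object of class `meta_profile`: list with `position` (bin
#'   centers relative to anchor), `sense`, `antisense`, `combined`
#'   (trimmed means), `n_anchors`, and per-anchor matrices in
#'   `per_anchor`.
#' @export
metaprofile <- function(anchors, reads, genome, flank = 5000, bin = 25,
                        trim = c(0.05, 0.95)) {
  if (is.data.frame(anchors)) {
    chrom <- anchors$chrom
    center <- region_centers(anchors)
  } else {
    chrom <- attr(anchors, "chrom")
    center <- as.numeric(anchors)
    if (is.null(chrom)) stop("anchor positions need a 'chrom' attribute")
  }
  if (length(center) == 0) stop("at least one anchor is required")
  len <- chrom_lengths(genome)
  inside <- center - flank >= 0 & center + flank <= len[chrom]
  if (!all(inside)) {
    warning(sprintf("dropping %d anchor(s) closer than %d bp to a chromosome end",
                    sum(!inside), flank))
    chrom <- chrom[inside]; center <- center[inside]
  }
  n <- length(center)
  if (n < 20)
    warning("fewer than 20 anchors: percentile trimming is unstable")
  if (inherits(reads, "read_set")) {
    big_n <- reads$library_size
    reads <- reads$reads
  } else big_n <- nrow(reads)
  nb <- as.integer(2 * flank / bin)
  layer <- function(df) {
    cov <- GenomicRanges::coverage(as_granges(df, genome))
    mat <- matrix(0, nrow = n, ncol = nb)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      starts <- rep(center[idx] - flank, each = nb) +
        rep(seq_len(nb) - 1, times = length(idx)) * bin + 1
      v <- IRanges::Views(cov[[ch]], start = starts, width = bin)
      mat[idx, ] <- matrix(as.numeric(IRanges::viewMeans(v)),
                           ncol = nb, byrow = TRUE)
    }
    mat * (1e6 / max(big_n, 1))
  }
  mats <- list(sense = layer(reads[reads$strand == "+", , drop = FALSE]),
               antisense = layer(reads[reads$strand == "-", , drop = FALSE]),
               combined = layer(reads))
  structure(list(position = seq_len(nb) * bin - flank - bin / 2,
                 sense = trimmed_col_means(mats$sense, trim[1], trim[2]),
                 antisense = trimmed_col_means(mats$antisense, trim[1],
                                               trim[2]),
                 combined = trimmed_col_means(mats$combined, trim[1],
                                              trim[2]),
                 n_anchors = n, bin = bin, flank = flank, trim = trim,
                 per_anchor = mats),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("metaprofile: %d anchors, %d bins of %d bp (+/- %d bp), trim [%g, %g]\n",
              x$n_anchors, length(x$position), x$bin, x$flank, x$trim[1],
              x$trim[2]))
  invisible(x)
}

#' Loess smoothing of a profile
#'
#' Locally weighted quadratic regression over the bin index; reproduces
#' constant and linear inputs exactly (to numerical precision).
#'
#' @param y Numeric vector (e.g. a metaprofile layer), or a `meta_profile`
#'   (smooths the chosen layer).
#' @param span Loess span in (0, 1]; must cover at least 4 points.
#' @param layer Layer to smooth when `y` is a `meta_profile`.
#' @return Numeric vector of smoothed values.
#' @export
loess_smooth <- function(y, span = 0.1, layer = "combined") {
  if (inherits(y, "meta_profile")) y <- y[[layer]]
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  n <- length(y)
  if (span * n < 4)
    stop("span too small for a local quadratic fit (needs >= 4 points)")
  x <- seq_len(n)
  fit <- stats::loess(y ~ x, span = span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  as.numeric(stats::predict(fit, x))
}

#' @noRd
binned_track_values <- function(track_n, chrom, center, flank, bin, genome) {
  nb <- as.integer(2 * flank / bin)
  len <- chrom_lengths(genome)
  starts <- center - flank + (seq_len(nb) - 1) * bin
  ends <- starts + bin
  ok <- starts >= 0 & ends <= len[[chrom]]
  out <- numeric(nb)
  if (any(ok)) {
    win <- genomic_intervals(rep(chrom, sum(ok)), starts[ok], ends[ok])
    out[ok] <- track_window_mean(track_n, win)
  }
  out
}

#' Z-scaled ChIP heatmap matrix around TSTR centers
#'
#' For each region, input-corrected depth-normalized ChIP coverage in
#' 25 bp bins over +/- 25 kb around the peak center (2000 columns), then
#' centered and scaled by the matrix-wide mean and SD so signal is
#' comparable across datasets. Rows are ordered by enrichment class:
#' none, k27ac_only, p300_only, both. Bins outside the chromosome are 0
#' before scaling.
#'
#' @param tstrs Region data frame with a `class` column (see
#'   [chip_enrichment_classify()]).
#' @param chip bedGraph data frame of the ChIP experiment.
#' @param input bedGraph data frame of the matched input.
#' @param genome Genome model.
#' @param flank Half-window (default 25000).
#' @param bin Bin width (default 25).
#' @return Object of class `heatmap_matrix`: list with `matrix` (rows =
#'   regions in class order), `row_index` (region name + class), `position`
#'   (bin centers relative to the anchor).
#' @export
heatmap_matrix <- function(tstrs, chip, input, genome, flank = 25000,
                           bin = 25) {
  stopifnot("class" %in% names(tstrs))
  ord <- order(as.integer(tstrs$class))
  tstrs <- tstrs[ord, , drop = FALSE]
  centers <- region_centers(tstrs)
  chip_n <- depth_normalize(chip)
  input_n <- depth_normalize(input)
  nb <- as.integer(2 * flank / bin)
  mat <- matrix(0, nrow = nrow(tstrs), ncol = nb)
  for (i in seq_len(nrow(tstrs))) {
    mat[i, ] <- binned_track_values(chip_n, tstrs$chrom[i], centers[i],
                                    flank, bin, genome) -
      binned_track_values(input_n, tstrs$chrom[i], centers[i], flank, bin,
                          genome)
  }
  s <- stats::sd(as.numeric(mat))
  if (is.na(s) || s == 0) {
    if (length(mat)) warning("constant heatmap matrix; returning zeros")
    mat[] <- 0
  } else {
    mat <- (mat - mean(mat)) / s
  }
  structure(list(matrix = mat,
                 row_index = data.frame(name = tstrs$name,
                                        class = tstrs$class),
                 position = seq_len(nb) * bin - flank - bin / 2),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat(sprintf("heatmap matrix: %d regions x %d bins; class order: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(levels(x$row_index$class), collapse = " < ")))
  invisible(x)
}
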