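# De novo discovery of intergenic transcribed regions: a sliding-window
# scan over 3'-extended reads, merging of qualifying windows into maximal
# enriched regions, removal of regions overlapping the annotation, and a
# read-subsampling saturation analysis.

#' Sliding-window scan for read-enriched regions
#'
#' Slides a window of `window` bp in steps of `step` bp across each
#' chromosome and retains every position where at least `min_reads`
#' extended reads intersect the window, ignoring strand (the discovery
#' threshold is deliberately strand-agnostic). Qualifying windows that
#' overlap or abut are merged into maximal enriched regions; each region is
#' annotated with its read count and the position of maximum combined
#' coverage (`peak_center`, leftmost on ties).
#'
#' @param reads A [read_set()] (or interval data frame) of reads already
#'   extended to the fragment length (see [extend_reads()]).
#' @param genome Genome model.
#' @param window Window size in bp (default 500).
#' @param step Step size in bp (default 50); must not exceed `window`.
#' @param min_reads Minimum reads per window (default 10, the conservative
#'   discovery threshold).
#' @return Interval data frame of enriched regions with columns
#'   `read_count` and `peak_center`.
#' @export
sliding_window_scan <- function(reads, genome, window = 500, step = 50,
                                min_reads = 10) {
  if (window < step) stop("config error: window must be >= step")
  if (min_reads < 1) stop("config error: min_reads must be >= 1")
  if (inherits(reads, "read_set")) reads <- reads$reads
  validate_intervals(reads, genome)
  if (nrow(reads) == 0) return(region_frame(empty_intervals()))
  len <- chrom_lengths(genome)
  gr_reads <- as_granges(reads, genome)
  parts <- lapply(genome$chrom, function(chrom) {
    L <- len[[chrom]]
    starts <- seq.int(0, max(0, L - 1), by = step)
    ends <- pmin(starts + window, L)
    win <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(starts + 1, ends))
    hits <- GenomicRanges::countOverlaps(win, gr_reads,
                                         ignore.strand = TRUE)
    keep <- hits >= min_reads
    if (!any(keep)) return(NULL)
    merged <- GenomicRanges::reduce(win[keep], min.gapwidth = 1L)
    data.frame(chrom = chrom,
               start = GenomicRanges::start(merged) - 1,
               end = GenomicRanges::end(merged),
               stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (length(parts) == 0) return(region_frame(empty_intervals()))
  regions <- do.call(rbind, parts)
  regions <- genomic_intervals(regions$chrom, regions$start, regions$end,
                               name = sprintf("region%04d",
                                              seq_len(nrow(regions))))
  regions$read_count <- count_overlaps(regions, reads)
  regions$peak_center <- peak_centers(regions, reads, genome)
  regions
}

#' @noRd
region_frame <- function(x) {
  x$read_count <- integer(nrow(x))
  x$peak_center <- numeric(nrow(x))
  x
}

#' Position of maximum combined read coverage within each region
#'
#' Leftmost position on ties; returned in 0-based coordinates.
#' @noRd
peak_centers <- function(regions, reads, genome) {
  if (nrow(regions) == 0) return(numeric(0))
  cov <- GenomicRanges::coverage(as_granges(reads, genome))
  vapply(seq_len(nrow(regions)), function(i) {
    rle <- cov[[regions$chrom[i]]]
    v <- IRanges::Views(rle, start = regions$start[i] + 1,
                        end = regions$end[i])
    as.numeric(IRanges::viewWhichMaxs(v)) - 1
  }, 0)
}

#' Remove regions overlapping the annotation
#'
#' Any region sharing at least one base with any exclusion interval
#' (genes, mRNAs, ESTs, rRNA) is removed; the removal count is reported
#' via `message()` and recorded in the `n_removed` attribute.
#'
#' @param regions Enriched-region data frame.
#' @param exclusions Interval data frame of annotation intervals.
#' @return The intergenic subset of `regions`.
#' @export
filter_annotated <- function(regions, exclusions) {
  if (nrow(regions) == 0) return(regions)
  drop <- overlaps_any(regions, exclusions)
  message(sprintf("filter_annotated: removed %d of %d regions overlapping annotation",
                  sum(drop), nrow(regions)))
  out <- regions[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Sequencing-depth saturation analysis
#'
#' Subsamples the read set at each fraction (without replacement, seeded),
#' reruns the scan + intergenic filter, and reports the number of
#' discovered regions. With `nested = TRUE` (default) a single permutation
#' is drawn and each fraction takes its leading slice, so smaller
#' subsamples are subsets of larger ones and region counts are
#' deterministically non-decreasing in the fraction.
#'
#' @param reads A [read_set()] of extended reads.
#' @param genome Genome model.
#' @param exclusions Annotation exclusion intervals.
#' @param fractions Increasing fractions in (0, 1].
#' @param seed Integer seed for the subsampling.
#' @param nested Use nested subsamples (one permutation) instead of
#'   independent draws per fraction.
#' @param ... Passed to [sliding_window_scan()].
#' @return Data frame with columns `fraction`, `n_reads`, `n_regions`.
#' @export
saturation_analysis <- function(reads, genome, exclusions,
                                fractions = seq(0.1, 1, by = 0.1),
                                seed = 1, nested = TRUE, ...) {
  if (any(fractions <= 0) || any(fractions > 1))
    stop("fractions must lie in (0, 1]")
  if (is.unsorted(fractions)) stop("fractions must be sorted increasing")
  df <- if (inherits(reads, "read_set")) reads$reads else reads
  n <- nrow(df)
  with_seed(seed, {
    perm <- sample.int(n)
    rows <- lapply(fractions, function(f) {
      k <- floor(f * n)
      idx <- if (nested) perm[seq_len(k)] else sample.int(n, k)
      sub <- df[sort(idx), , drop = FALSE]
      regions <- sliding_window_scan(sub, genome, ...)
      regions <- suppressMessages(filter_annotated(regions, exclusions))
      data.frame(fraction = f, n_reads = k, n_regions = nrow(regions))
    })
  })
  do.call(rbind, rows)
}
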