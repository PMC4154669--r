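#' Construct a table of genomic intervals
#'
#' Intervals are plain data frames in BED convention: 0-based, half-open
#' `[start, end)` coordinates, strand one of `"+"`, `"-"` or `"."`
#' (unstranded). All pipeline stages exchange this representation.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start positions.
#' @param end Integer vector, exclusive end positions.
#' @param name Optional feature names (recycled).
#' @param score Optional numeric scores (recycled).
#' @param strand Strand, `"+"`, `"-"` or `"."` (recycled).
#' @return A data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), name = ".", score = 0,
                              strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  x <- data.frame(chrom = rep_len(as.character(chrom), n),
                  start = rep_len(as.numeric(start), n),
                  end = rep_len(as.numeric(end), n),
                  name = rep_len(as.character(name), n),
                  score = rep_len(as.numeric(score), n),
                  strand = rep_len(as.character(strand), n),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

#' Validate an interval table
#'
#' @param x Interval data frame.
#' @param genome Optional genome model (see [build_genome()]); when given,
#'   intervals must lie within chromosome bounds.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, genome = NULL) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop("interval table must have columns chrom, start, end")
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop("interval coordinates must not be NA")
  if (any(x$start < 0)) stop("negative start coordinate")
  if (any(x$start >= x$end)) stop("empty or inverted interval (start >= end)")
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", ".")))
    stop("strand must be '+', '-' or '.'")
  if (!is.null(genome)) {
    len <- chrom_lengths(genome)
    if (!all(x$chrom %in% names(len)))
      stop("interval on chromosome absent from genome")
    if (any(x$end > len[x$chrom]))
      stop("interval extends past chromosome end")
  }
  invisible(x)
}

#' @noRd
empty_intervals <- function() {
  genomic_intervals()
}

#' Convert an interval table to a GRanges object
#'
#' Internal bridge to the Bioconductor interval machinery; shifts to
#' 1-based closed coordinates.
#' @noRd
as_granges <- function(x, genome = NULL) {
  if (nrow(x) == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    strand <- if ("strand" %in% names(x)) {
      ifelse(x$strand == ".", "*", x$strand)
    } else "*"
    gr <- GenomicRanges::GRanges(
      seqnames = x$chrom,
      ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
      strand = strand)
  }
  if (!is.null(genome)) {
    len <- chrom_lengths(genome)
    GenomeInfoDb::seqlevels(gr) <- names(len)
    GenomeInfoDb::seqlengths(gr) <- unname(len)
  }
  gr
}

#' Named vector of chromosome lengths from a genome model
#' @param genome Genome model data frame with columns `chrom`, `length`.
#' @return Named numeric vector.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(genome$length, genome$chrom)
}

# align seqlevels so findOverlaps does not warn on disjoint chromosome sets
#' @noRd
pair_granges <- function(a, b) {
  ga <- as_granges(a)
  gb <- as_granges(b)
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  list(ga, gb)
}

#' Find all overlapping pairs between two interval sets
#'
#' Reports every pair of intervals from `a` and `b` that share at least one
#' base on the same chromosome, ignoring strand. Half-open adjacency
#' (`end == start`) is not an overlap.
#'
#' @param a,b Interval data frames.
#' @return Data frame with columns `query` (row index into `a`) and
#'   `subject` (row index into `b`).
#' @export
overlap_query <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  g <- pair_granges(a, b)
  hits <- GenomicRanges::findOverlaps(g[[1]], g[[2]], ignore.strand = TRUE)
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

#' Which intervals in `a` overlap any interval in `b`?
#' @inheritParams overlap_query
#' @return Logical vector along rows of `a`.
#' @export
overlaps_any <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  g <- pair_granges(a, b)
  IRanges::overlapsAny(g[[1]], g[[2]], ignore.strand = TRUE)
}

#' Count for each interval in `a` the overlapping intervals in `b`
#' @inheritParams overlap_query
#' @return Integer vector along rows of `a`.
#' @export
count_overlaps <- function(a, b) {
  if (nrow(a) == 0) return(integer(0))
  if (nrow(b) == 0) return(rep(0L, nrow(a)))
  g <- pair_granges(a, b)
  GenomicRanges::countOverlaps(g[[1]], g[[2]], ignore.strand = TRUE)
}

#' Extend reads in the 3' direction to a fixed total length
#'
#' RNA-seq fragments average ~200 bp while only 50 bp is sequenced, so
#' alignments are extended to the fragment length before any counting:
#' a `+` read `[s, e)` becomes `[s, s + total_length)` and a `-` read
#' becomes `[e - total_length, e)`, clipped to chromosome bounds.
#'
#' @param reads Interval data frame of read alignments (or a `read_set`).
#' @param total_length Target total read length in bp (default 200).
#' @param genome Genome model used for clipping.
#' @return Object of the same kind as `reads` with extended intervals.
#' @export
extend_reads <- function(reads, total_length = 200, genome) {
  if (inherits(reads, "read_set")) {
    reads$reads <- extend_reads(reads$reads, total_length, genome)
    reads$extended <- total_length
    return(reads)
  }
  validate_intervals(reads)
  if (nrow(reads) == 0) return(reads)
  if (any(reads$strand == "."))
    stop("unstranded read: strand is required for 3' extension")
  if (any(reads$end - reads$start > total_length))
    stop("total_length shorter than an existing read")
  len <- chrom_lengths(genome)
  plus <- reads$strand == "+"
  reads$end[plus] <- pmin(reads$start[plus] + total_length,
                          len[reads$chrom[plus]])
  reads$start[!plus] <- pmax(reads$end[!plus] - total_length, 0)
  validate_intervals(reads, genome)
  reads
}

#' Binned read coverage across a genome
#'
#' Depth of (extended) reads per fixed-size bin, optionally partitioned by
#' strand. Values are mean depth over each bin, so
#' `sum(values * bin_width)` equals the total clipped read bases.
#'
#' @param reads Interval data frame of reads (or a `read_set`).
#' @param genome Genome model.
#' @param bin Bin size in bp (default 1).
#' @param strand_mode `"combined"` or `"by_strand"`.
#' @return Object of class `coverage_track`: list with `bin`, `strand_mode`
#'   and `values`, a per-chromosome list of numeric vectors (for
#'   `"by_strand"`, a list with elements `sense` (+), `antisense` (-) and
#'   `combined`).
#' @export
coverage_track <- function(reads, genome, bin = 1L,
                           strand_mode = c("combined", "by_strand")) {
  strand_mode <- match.arg(strand_mode)
  if (inherits(reads, "read_set")) reads <- reads$reads
  validate_intervals(reads, genome)
  one <- function(df) binned_depth(df, genome, bin)
  values <- if (strand_mode == "combined") {
    one(reads)
  } else {
    list(sense = one(reads[reads$strand == "+", , drop = FALSE]),
         antisense = one(reads[reads$strand == "-", , drop = FALSE]),
         combined = one(reads))
  }
  structure(list(bin = bin, strand_mode = strand_mode, genome = genome,
                 values = values),
            class = "coverage_track")
}

#' @noRd
binned_depth <- function(reads, genome, bin) {
  len <- chrom_lengths(genome)
  out <- vector("list", length(len))
  names(out) <- names(len)
  gr <- as_granges(reads, genome)
  cov <- GenomicRanges::coverage(gr)
  for (chrom in names(len)) {
    L <- len[[chrom]]
    rle <- cov[[chrom]]
    nb <- ceiling(L / bin)
    starts <- seq.int(1L, by = bin, length.out = nb)
    widths <- pmin(bin, L - starts + 1L)
    v <- IRanges::Views(rle, start = starts, width = widths)
    out[[chrom]] <- as.numeric(IRanges::viewSums(v)) / widths
  }
  out
}

#' Convert a coverage track to bedGraph-style intervals
#'
#' Adjacent equal-valued bins are merged; zero-valued runs are kept so the
#' records tile each chromosome.
#'
#' @param track A `coverage_track` (combined mode or one strand layer).
#' @param layer For by-strand tracks, which layer to export.
#' @return Interval data frame with `score` carrying the depth.
#' @export
track_to_intervals <- function(track, layer = "combined") {
  vals <- track$values
  if (track$strand_mode == "by_strand") vals <- vals[[layer]]
  len <- chrom_lengths(track$genome)
  parts <- lapply(names(vals), function(chrom) {
    v <- vals[[chrom]]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    data.frame(chrom = chrom,
               start = starts_bin * track$bin,
               end = pmin(ends_bin * track$bin, len[[chrom]]),
               name = ".", score = r$values, strand = ".",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Mean bedGraph value over query windows
#'
#' Overlap-weighted mean of a bedGraph-style scored track over each window;
#' positions not covered by any record count as 0.
#'
#' @param track Interval data frame with `score` (non-overlapping records).
#' @param windows Interval data frame of query windows.
#' @return Numeric vector along rows of `windows`.
#' @export
track_window_mean <- function(track, windows) {
  if (nrow(windows) == 0) return(numeric(0))
  out <- numeric(nrow(windows))
  if (nrow(track) == 0) return(out)
  hits <- overlap_query(windows, track)
  if (nrow(hits) > 0) {
    ov <- pmin(windows$end[hits$query], track$end[hits$subject]) -
      pmax(windows$start[hits$query], track$start[hits$subject])
    contrib <- ov * track$score[hits$subject]
    sums <- tapply(contrib, hits$query, sum)
    idx <- as.integer(names(sums))
    out[idx] <- as.numeric(sums) / (windows$end[idx] - windows$start[idx])
  }
  out
}

#' Fixed-width windows centered on positions
#'
#' @param chrom Chromosome names.
#' @param center Center positions (bp).
#' @param width Window width in bp.
#' @param genome Optional genome model; windows are clipped to bounds.
#' @return Interval data frame of windows `[center - width/2, center + width/2)`.
#' @export
center_windows <- function(chrom, center, width, genome = NULL) {
  half <- width / 2
  start <- floor(center - half)
  end <- start + width
  if (!is.null(genome)) {
    len <- chrom_lengths(genome)
    start <- pmax(start, 0)
    end <- pmin(end, len[chrom])
  } else {
    start <- pmax(start, 0)
  }
  genomic_intervals(chrom = chrom, start = start, end = end)
}

#' Bundle strand-specific unique reads with their library size
#'
#' The library size N is the number of uniquely mapped reads excluding
#' reads that overlap ribosomal RNA regions; it is the denominator for
#' RPKM and the two-proportion z-test.
#'
#' @param reads Interval data frame of uniquely mapped reads.
#' @param rrna Interval data frame of rRNA regions (may be empty).
#' @param tissue Tissue label.
#' @return Object of class `read_set`: list with `reads`, `library_size`,
#'   `tissue`.
#' @export
read_set <- function(reads, rrna = empty_intervals(), tissue = "tissue") {
  validate_intervals(reads)
  n_rrna <- if (nrow(reads)) sum(overlaps_any(reads, rrna)) else 0L
  structure(list(reads = reads,
                 library_size = nrow(reads) - n_rrna,
                 n_rrna = n_rrna,
                 tissue = tissue),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set '%s': %d unique reads, N = %d (%d rRNA-overlapping excluded)\n",
              x$tissue, nrow(x$reads), x$library_size, x$n_rrna))
  invisible(x)
}
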