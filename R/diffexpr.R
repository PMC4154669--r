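# Statistical core: differential transcription between two tissues by the
# two-proportion z-test on read counts, TSTR calling, RPKM, specificity and
# directionality indices, enhancer fold changes, concordance statistics and
# qPCR candidate selection.

#' Two-proportion z-test on region read counts
#'
#' Tests whether the proportion of library reads falling in a region
#' differs between two tissues. With `p_hat = n / N` per tissue and the
#' pooled proportion `p0 = (n_A + n_B) / (N_A + N_B)`,
#' `z = (p_hat_A - p_hat_B) / sqrt(p0 (1 - p0) (1/N_A + 1/N_B))` and the
#' two-sided p-value is `2 * pnorm(-|z|)`. Degenerate pooled proportions
#' (`p0` of 0 or 1) return `z = 0, p = 1`: nothing (or everything)
#' observed carries no evidence of a difference. Vectorized.
#'
#' @param n_a,n_b Reads within the region per tissue.
#' @param big_n_a,big_n_b Library sizes (mappable reads excluding rRNA).
#' @return Data frame with columns `p_hat_a`, `p_hat_b`, `p0`, `z`, `p`.
#' @export
two_proportion_z <- function(n_a, n_b, big_n_a, big_n_b) {
  k <- max(length(n_a), length(n_b))
  n_a <- rep_len(n_a, k); n_b <- rep_len(n_b, k)
  big_n_a <- rep_len(big_n_a, k); big_n_b <- rep_len(big_n_b, k)
  if (any(big_n_a <= 0) || any(big_n_b <= 0))
    stop("library sizes must be positive")
  if (any(n_a < 0) || any(n_b < 0)) stop("negative read count")
  if (any(n_a > big_n_a) || any(n_b > big_n_b))
    stop("input error: region count exceeds library size")
  p_hat_a <- n_a / big_n_a
  p_hat_b <- n_b / big_n_b
  p0 <- (n_a + n_b) / (big_n_a + big_n_b)
  se <- sqrt(p0 * (1 - p0) * (1 / big_n_a + 1 / big_n_b))
  z <- ifelse(p0 <= 0 | p0 >= 1, 0, (p_hat_a - p_hat_b) / se)
  data.frame(p_hat_a = p_hat_a, p_hat_b = p_hat_b, p0 = p0, z = z,
             p = ifelse(z == 0, 1, 2 * stats::pnorm(-abs(z))))
}

#' Count reads intersecting fixed windows
#'
#' Strand-agnostic by default; pass `strand` to restrict. This single
#' counting convention (extended reads with >= 1 bp intersection) is shared
#' by the differential test, the background calibration and the enhancer
#' expression summaries.
#'
#' @param reads A [read_set()] or interval data frame of (extended) reads.
#' @param windows Interval data frame.
#' @param strand Optional `"+"` or `"-"`.
#' @return Integer vector along rows of `windows`.
#' @export
count_reads_in_windows <- function(reads, windows, strand = NULL) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  if (!is.null(strand))
    reads <- reads[reads$strand == strand, , drop = FALSE]
  count_overlaps(windows, reads)
}

#' Per-region counts in 2 kb windows around peak centers
#'
#' @param regions Region data frame (uses `peak_center` when present,
#'   otherwise the interval midpoint).
#' @param rs_a,rs_b [read_set()] per tissue (extended reads).
#' @param window Window width in bp (default 2000).
#' @param genome Optional genome model for clipping.
#' @return `regions` with columns `win_start`, `win_end`, `n_a`, `n_b` and
#'   strand-split counts `f_a`, `r_a`, `f_b`, `r_b`.
#' @export
region_counts <- function(regions, rs_a, rs_b, window = 2000, genome = NULL) {
  centers <- if ("peak_center" %in% names(regions)) regions$peak_center
  else floor((regions$start + regions$end) / 2)
  win <- center_windows(regions$chrom, centers, window, genome)
  regions$win_start <- win$start
  regions$win_end <- win$end
  regions$n_a <- count_reads_in_windows(rs_a, win)
  regions$n_b <- count_reads_in_windows(rs_b, win)
  regions$f_a <- count_reads_in_windows(rs_a, win, strand = "+")
  regions$r_a <- count_reads_in_windows(rs_a, win, strand = "-")
  regions$f_b <- count_reads_in_windows(rs_b, win, strand = "+")
  regions$r_b <- count_reads_in_windows(rs_b, win, strand = "-")
  regions
}

#' Reads per kilobase per million mapped reads
#'
#' @param count Read count in the region.
#' @param region_length Region length in bp.
#' @param big_n Library size (mappable reads excluding rRNA).
#' @param visualization_floor If `TRUE`, values below 2^-9 are raised to
#'   2^-9 (a plotting convention for log-scale dot plots).
#' @return Numeric vector.
#' @export
rpkm <- function(count, region_length, big_n, visualization_floor = FALSE) {
  if (any(region_length <= 0)) stop("region_length must be positive")
  if (any(big_n <= 0)) stop("library size must be positive")
  x <- count / (region_length / 1000) / (big_n / 1e6)
  if (visualization_floor) x <- pmax(x, 2^-9)
  x
}

#' Tissue-specificity index
#'
#' `(s - u) / (s + u)` where `s` is expression in the matching tissue and
#' `u` in the other; ranges -1 (exclusive to the other tissue) to 1
#' (exclusive to the matching tissue). `s + u = 0` returns 0 with a
#' warning.
#'
#' @param s,u Non-negative expression values (counts or RPKM).
#' @return Numeric vector in `[-1, 1]`.
#' @export
specificity_index <- function(s, u) {
  if (any(s < 0) || any(u < 0)) stop("input error: negative expression")
  tot <- s + u
  if (any(tot == 0)) warning("specificity index undefined (s + u = 0); returning 0")
  ifelse(tot == 0, 0, (s - u) / tot)
}

#' Directionality index
#'
#' `|f - r| / (f + r)` contrasting forward- and reverse-strand read counts
#' at a locus: 0 = balanced bidirectional transcription, 1 =
#' unidirectional. `f + r = 0` returns 0 with a warning.
#'
#' @param f,r Non-negative strand-specific counts.
#' @return Numeric vector in `[0, 1]`.
#' @export
directionality_index <- function(f, r) {
  if (any(f < 0) || any(r < 0)) stop("input error: negative count")
  tot <- f + r
  if (any(tot == 0)) warning("directionality index undefined (f + r = 0); returning 0")
  ifelse(tot == 0, 0, abs(f - r) / tot)
}

#' Enhancer expression fold change with zero substitution
#'
#' For enhancers expressed in only one tissue the zero count is arbitrarily
#' set to 1 so an absolute fold change is defined; fold change is the
#' higher expression divided by the lower (so always >= 1) and `log2fc` is
#' signed positive toward tissue A. The p-value comes from the
#' two-proportion z-test on the raw counts.
#'
#' @param n_a,n_b Read counts in the enhancer's 2 kb center window.
#' @param big_n_a,big_n_b Library sizes.
#' @return Data frame with `fold`, `log2fc`, `z`, `p` (a volcano-plot
#'   record per enhancer).
#' @export
enhancer_fold_change <- function(n_a, n_b, big_n_a, big_n_b) {
  zt <- two_proportion_z(n_a, n_b, big_n_a, big_n_b)
  a <- pmax(n_a, 1)
  b <- pmax(n_b, 1)
  data.frame(fold = pmax(a, b) / pmin(a, b), log2fc = log2(a / b),
             z = zt$z, p = zt$p)
}

#' Fraction of enhancers concordant with their annotated tissue
#'
#' An enhancer is concordant when its read count is strictly higher in the
#' tissue where its in vivo activity was annotated; ties count as
#' discordant.
#'
#' @param tissue Annotated activity tissue per enhancer.
#' @param n_a,n_b Read counts per tissue.
#' @param tissues The two tissue labels (order matching `n_a`, `n_b`).
#' @return List with `overall` fraction, `by_tissue` named vector, and
#'   `concordant` logical vector.
#' @export
concordance_fraction <- function(tissue, n_a, n_b, tissues = c("A", "B")) {
  if (length(tissue) == 0) stop("empty enhancer catalog")
  if (!all(tissue %in% tissues)) stop("unknown tissue label in catalog")
  conc <- ifelse(tissue == tissues[1], n_a > n_b, n_b > n_a)
  by_tissue <- vapply(tissues, function(t) mean(conc[tissue == t]), 0)
  list(overall = mean(conc), by_tissue = by_tissue, concordant = conc)
}

#' Exact two-sided binomial concordance test
#'
#' Doubled-smaller-tail convention, capped at 1:
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))` with
#' `X ~ Binomial(n, p0)`. Used for the "k of n enhancers most expressed in
#' the predicted tissue" design where guessing has success probability
#' `p0` (1/3 for a three-tissue comparison).
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability, in (0, 1).
#' @return Two-sided exact p-value.
#' @export
exact_concordance_test <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  lower <- stats::pbinom(k, n, p0)
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Call tissue-specifically transcribed regions
#'
#' Assigns each region to the tissue with the higher read proportion when
#' the two-proportion z-test is significant (`p < alpha`, strict);
#' otherwise the region stays unassigned (the grey-dot class of expressed
#' but not tissue-specific regions).
#'
#' @param counted Output of [region_counts()].
#' @param big_n_a,big_n_b Library sizes.
#' @param alpha Significance level (default 0.01).
#' @param tissues The two tissue labels.
#' @return `counted` with test columns plus `tissue` (label or `"none"`).
#' @export
call_tstrs <- function(counted, big_n_a, big_n_b, alpha = 0.01,
                       tissues = c("A", "B")) {
  zt <- two_proportion_z(counted$n_a, counted$n_b, big_n_a, big_n_b)
  counted$z <- zt$z
  counted$p <- zt$p
  counted$tissue <- ifelse(zt$p >= alpha, "none",
                           ifelse(zt$p_hat_a > zt$p_hat_b, tissues[1],
                                  tissues[2]))
  counted
}

#' Select qPCR validation candidates from top-ranked TSTRs
#'
#' Ranks TSTRs by absolute z score (descending), keeps the top 30 percent
#' (ceiling), and samples `m` uniformly without replacement under the seed.
#'
#' @param tstrs Data frame with a `z` column.
#' @param m Number of candidates.
#' @param seed Integer seed.
#' @param top_fraction Fraction of top-ranked regions forming the pool.
#' @return The selected rows of `tstrs`.
#' @export
select_qpcr_candidates <- function(tstrs, m, seed = 1, top_fraction = 0.3) {
  pool_size <- ceiling(top_fraction * nrow(tstrs))
  if (m > pool_size)
    stop(sprintf("m (%d) exceeds candidate pool size (%d)", m, pool_size))
  pool <- tstrs[order(-abs(tstrs$z)), , drop = FALSE][seq_len(pool_size), ,
                                                      drop = FALSE]
  with_seed(seed, pool[sample.int(pool_size, m), , drop = FALSE])
}

#' Discover tissue-specifically transcribed regions from two read sets
#'
#' The central fitting step of the pipeline: extends reads 200 bp in the 3'
#' direction, scans each tissue for read-enriched regions (>= `min_reads`
#' per `window_scan` bp window, strand-agnostic), removes regions
#' overlapping the annotation, merges the two tissues' surviving regions
#' into one candidate set, counts reads in 2 kb windows around each peak
#' center, and calls TSTRs at `p < alpha` by the two-proportion z-test.
#' RPKM, tissue-specificity and per-tissue directionality indices are
#' attached to every candidate.
#'
#' @param rs_a,rs_b [read_set()] per tissue (raw alignments; extension is
#'   applied here unless `already_extended`).
#' @param genome Genome model.
#' @param exclusions Annotation exclusion intervals (genes, mRNAs, ESTs).
#' @param extension Total extended read length in bp (default 200).
#' @param window_scan,step,min_reads Sliding-window scan parameters.
#' @param expr_window Expression window width around peak centers (bp).
#' @param alpha TSTR significance level.
#' @param already_extended Set when `rs_a`/`rs_b` are already extended.
#' @return Object of class `tstr_fit`: list with `table` (one row per
#'   candidate region), `regions_per_tissue`, library sizes, tissue labels
#'   and the parameters used.
#' @export
tstr_discover <- function(rs_a, rs_b, genome, exclusions,
                          extension = 200, window_scan = 500, step = 50,
                          min_reads = 10, expr_window = 2000, alpha = 0.01,
                          already_extended = FALSE) {
  stopifnot(inherits(rs_a, "read_set"), inherits(rs_b, "read_set"))
  tissues <- c(rs_a$tissue, rs_b$tissue)
  if (!already_extended) {
    rs_a <- extend_reads(rs_a, extension, genome)
    rs_b <- extend_reads(rs_b, extension, genome)
  }
  per_tissue <- lapply(list(rs_a, rs_b), function(rs) {
    regions <- sliding_window_scan(rs, genome, window = window_scan,
                                   step = step, min_reads = min_reads)
    suppressMessages(filter_annotated(regions, exclusions))
  })
  names(per_tissue) <- tissues
  both <- rbind(per_tissue[[1]][, c("chrom", "start", "end")],
                per_tissue[[2]][, c("chrom", "start", "end")])
  pooled <- rbind(rs_a$reads, rs_b$reads)
  if (nrow(both) > 0) {
    merged <- GenomicRanges::reduce(as_granges(both), ignore.strand = TRUE)
    union <- genomic_intervals(
      as.character(GenomicRanges::seqnames(merged)),
      GenomicRanges::start(merged) - 1, GenomicRanges::end(merged),
      name = sprintf("TSTR%04d", seq_along(merged)))
    union$peak_center <- peak_centers(union, pooled, genome)
  } else {
    union <- empty_intervals()
    union$peak_center <- numeric(0)
  }
  counted <- region_counts(union, rs_a, rs_b, window = expr_window,
                           genome = genome)
  tab <- call_tstrs(counted, rs_a$library_size, rs_b$library_size,
                    alpha = alpha, tissues = tissues)
  tab$rpkm_a <- rpkm(tab$n_a, expr_window, rs_a$library_size)
  tab$rpkm_b <- rpkm(tab$n_b, expr_window, rs_b$library_size)
  hi <- ifelse(tab$tissue == tissues[2], "b",
               ifelse(tab$tissue == tissues[1], "a",
                      ifelse(tab$rpkm_a >= tab$rpkm_b, "a", "b")))
  s <- ifelse(hi == "a", tab$rpkm_a, tab$rpkm_b)
  u <- ifelse(hi == "a", tab$rpkm_b, tab$rpkm_a)
  tab$si <- suppressWarnings(specificity_index(s, u))
  tab$di_a <- suppressWarnings(directionality_index(tab$f_a, tab$r_a))
  tab$di_b <- suppressWarnings(directionality_index(tab$f_b, tab$r_b))
  structure(list(table = tab, regions_per_tissue = per_tissue,
                 library_sizes = stats::setNames(
                   c(rs_a$library_size, rs_b$library_size), tissues),
                 tissues = tissues,
                 params = list(extension = extension,
                               window_scan = window_scan, step = step,
                               min_reads = min_reads,
                               expr_window = expr_window, alpha = alpha)),
            class = "tstr_fit")
}

#' @export
print.tstr_fit <- function(x, ...) {
  tt <- table(factor(x$table$tissue, levels = c(x$tissues, "none")))
  cat("TSTR discovery fit\n")
  cat(sprintf("  candidate intergenic regions: %d\n", nrow(x$table)))
  for (t in x$tissues)
    cat(sprintf("  %s-specific TSTRs (p < %g): %d\n", t, x$params$alpha,
                tt[[t]]))
  cat(sprintf("  not tissue-specific: %d\n", tt[["none"]]))
  invisible(x)
}

#' @export
summary.tstr_fit <- function(object, ...) {
  tab <- object$table
  out <- list(
    n_regions = nrow(tab),
    n_tstr = stats::setNames(
      vapply(object$tissues, function(t) sum(tab$tissue == t), 0L),
      object$tissues),
    library_sizes = object$library_sizes,
    params = object$params,
    si_summary = if (nrow(tab)) summary(tab$si) else NULL,
    di_summary = if (nrow(tab)) summary(c(tab$di_a, tab$di_b)) else NULL)
  class(out) <- "summary.tstr_fit"
  out
}

#' @export
print.summary.tstr_fit <- function(x, ...) {
  cat("TSTR discovery summary\n")
  cat(sprintf("  regions tested: %d\n", x$n_regions))
  for (t in names(x$n_tstr))
    cat(sprintf("  %s-specific TSTRs: %d\n", t, x$n_tstr[[t]]))
  cat(sprintf("  library sizes: %s\n",
              paste(sprintf("%s=%d", names(x$library_sizes),
                            x$library_sizes), collapse = ", ")))
  if (!is.null(x$si_summary)) {
    cat("  specificity index:\n")
    print(x$si_summary)
  }
  invisible(x)
}

#' Volcano / dot-plot view of a TSTR fit
#'
#' `type = "volcano"` plots signed log2 RPKM fold change against -log10 p;
#' `type = "dots"` plots per-tissue log2 RPKM (with the 2^-9 visualization
#' floor) colored by call.
#'
#' @param x A `tstr_fit`.
#' @param type Plot type.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tstr_fit <- function(x, type = c("volcano", "dots"), ...) {
  type <- match.arg(type)
  tab <- x$table
  col <- ifelse(tab$tissue == x$tissues[1], "red3",
                ifelse(tab$tissue == x$tissues[2], "cyan3", "grey60"))
  if (type == "volcano") {
    fc <- log2(pmax(tab$rpkm_a, 2^-9) / pmax(tab$rpkm_b, 2^-9))
    graphics::plot(fc, -log10(pmax(tab$p, 1e-300)), col = col, pch = 16,
                   xlab = sprintf("log2 RPKM fold change (%s / %s)",
                                  x$tissues[1], x$tissues[2]),
                   ylab = "-log10 p", ...)
  } else {
    graphics::plot(log2(pmax(tab$rpkm_a, 2^-9)),
                   log2(pmax(tab$rpkm_b, 2^-9)), col = col, pch = 16,
                   xlab = sprintf("log2 RPKM (%s)", x$tissues[1]),
                   ylab = sprintf("log2 RPKM (%s)", x$tissues[2]), ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
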