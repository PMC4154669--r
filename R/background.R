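# Random-region background calibration: size-matched control regions drawn
# from annotation-free space, a 100-iteration background estimate with a
# normal fit, and the threshold table comparing validated enhancers against
# that background (the calibration behind the >= 10-read discovery
# threshold).

#' Draw random size-matched control regions
#'
#' Places `count` regions with exactly the given sizes, uniformly over all
#' admissible positions (rejection sampling under the seed), with zero
#' overlap with the exclusion set. Control regions may overlap each other,
#' as independent draws.
#'
#' @param count Number of regions.
#' @param sizes Region sizes in bp (recycled to `count`).
#' @param exclusions Interval data frame to avoid (genes, mRNAs, ESTs).
#' @param genome Genome model.
#' @param seed Integer seed.
#' @param retries_per Rejection-sampling budget per region.
#' @return Interval data frame of `count` regions.
#' @export
random_control_regions <- function(count, sizes, exclusions, genome,
                                   seed = 1, retries_per = 1000) {
  if (count == 0) return(empty_intervals())
  sizes <- rep_len(sizes, count)
  len <- chrom_lengths(genome)
  excl <- lapply(stats::setNames(genome$chrom, genome$chrom), function(ch) {
    sel <- exclusions$chrom == ch
    list(start = exclusions$start[sel], end = exclusions$end[sel])
  })
  with_seed(seed, {
    out_chrom <- character(count); out_start <- numeric(count)
    for (i in seq_len(count)) {
      ok <- FALSE
      for (try in seq_len(retries_per)) {
        chrom <- sample_chrom(genome)
        if (len[[chrom]] <= sizes[i]) next
        start <- floor(stats::runif(1, 0, len[[chrom]] - sizes[i]))
        e <- excl[[chrom]]
        if (!any(e$start < start + sizes[i] & e$end > start)) {
          out_chrom[i] <- chrom; out_start[i] <- start
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("placement failure: no admissible position for control region (retry budget exhausted)")
    }
    genomic_intervals(out_chrom, out_start, out_start + sizes,
                      name = sprintf("control%04d", seq_len(count)))
  })
}

#' Iterated background estimation over random control regions
#'
#' For each of `iterations` rounds, draws fresh size-matched control
#' regions, counts reads (strand-agnostic) in a fixed-width window around
#' each control midpoint, and records the fraction of controls with at
#' least `t` reads for every threshold `t`. The per-threshold mean and SD
#' across iterations form a normal background model.
#'
#' @param reads A [read_set()] of extended reads.
#' @param sizes Control region sizes (typically the enhancer catalog's
#'   sizes, giving the same number and size of sequences).
#' @param exclusions Annotation exclusions.
#' @param genome Genome model.
#' @param thresholds Integer read-count thresholds (>= 1).
#' @param iterations Number of iterations (default 100; must be >= 2).
#' @param window Window width around control midpoints in bp (default
#'   1000).
#' @param seed Integer seed.
#' @return Object of class `background_model`: list with `thresholds`,
#'   `mean`, `sd`, `fractions` (iterations x thresholds matrix),
#'   `iterations`, `window`.
#' @export
background_iterate <- function(reads, sizes, exclusions, genome,
                               thresholds = c(1, 10), iterations = 100,
                               window = 1000, seed = 1) {
  if (iterations < 2) stop("iterations must be >= 2 (SD undefined otherwise)")
  if (any(thresholds < 1)) stop("thresholds must be >= 1")
  fractions <- matrix(0, nrow = iterations, ncol = length(thresholds),
                      dimnames = list(NULL, paste0("t", thresholds)))
  for (it in seq_len(iterations)) {
    ctrl <- random_control_regions(length(sizes), sizes, exclusions, genome,
                                   seed = seed + it)
    mid <- floor((ctrl$start + ctrl$end) / 2)
    win <- center_windows(ctrl$chrom, mid, window, genome)
    counts <- count_reads_in_windows(reads, win)
    fractions[it, ] <- vapply(thresholds,
                              function(t) mean(counts >= t), 0)
  }
  structure(list(thresholds = thresholds,
                 mean = colMeans(fractions),
                 sd = apply(fractions, 2, stats::sd),
                 fractions = fractions,
                 iterations = iterations, window = window),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background model: %d iterations, %d bp windows\n",
              x$iterations, x$window))
  print(data.frame(threshold = x$thresholds, mean = x$mean, sd = x$sd,
                   row.names = NULL))
  invisible(x)
}

#' Upper-tail normal p-value against the background model
#'
#' `p = 1 - Phi((observed - mean) / sd)` for the chosen threshold. A
#' degenerate background (SD 0) returns 0 or 1 by the sign of the
#' deviation, with a warning.
#'
#' @param observed_fraction Observed fraction (e.g. of enhancers meeting
#'   the threshold).
#' @param model A `background_model`.
#' @param threshold Which threshold's background to use.
#' @return Upper-tail p-value.
#' @export
background_pvalue <- function(observed_fraction, model, threshold) {
  i <- match(threshold, model$thresholds)
  if (is.na(i)) stop("threshold not in background model")
  m <- model$mean[i]; s <- model$sd[i]
  if (s == 0) {
    warning("background SD is 0; p-value degenerate")
    return(if (observed_fraction > m) 0 else if (observed_fraction < m) 1
           else 0.5)
  }
  stats::pnorm((observed_fraction - m) / s, lower.tail = FALSE)
}

#' Enhancer-vs-background threshold table
#'
#' For each threshold of the background model, reports the percentage of
#' catalog enhancers with at least that many reads in the window around
#' their midpoint, the average percentage of random control regions, the
#' enhancer/control fold ratio and the background p-value.
#'
#' @param enhancers Interval data frame (the validated-enhancer catalog).
#' @param reads A [read_set()] of extended reads.
#' @param model A `background_model` (its `window` is reused).
#' @param genome Genome model.
#' @return Data frame with columns `threshold`, `pct_enhancers`,
#'   `pct_controls`, `fold_ratio`, `p`.
#' @export
threshold_report <- function(enhancers, reads, model, genome) {
  if (nrow(enhancers) == 0) stop("empty enhancer catalog")
  mid <- floor((enhancers$start + enhancers$end) / 2)
  win <- center_windows(enhancers$chrom, mid, model$window, genome)
  counts <- count_reads_in_windows(reads, win)
  rows <- lapply(seq_along(model$thresholds), function(i) {
    t <- model$thresholds[i]
    fe <- mean(counts >= t)
    fc <- model$mean[i]
    data.frame(threshold = t,
               pct_enhancers = 100 * fe,
               pct_controls = 100 * fc,
               fold_ratio = if (fe == 0) 0 else if (fc > 0) fe / fc else NA_real_,
               p = suppressWarnings(background_pvalue(fe, model, t)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
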