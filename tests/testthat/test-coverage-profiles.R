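test_that("metaprofile of uniform coverage is flat; duplicates are no-ops", {
  g <- tiny_genome(1, 1e5)
  # one synthetic fragment covering the whole chromosome: depth 1 everywhere
  rs <- read_set(genomic_intervals("chr1", 0, 1e5, strand = "+"))
  anchors <- genomic_intervals("chr1", c(2e4, 5e4, 8e4) - 500,
                               c(2e4, 5e4, 8e4) + 500)
  prof <- suppressWarnings(metaprofile(anchors, rs, g))
  expect_equal(length(prof$combined), 400)
  expect_true(all(prof$combined == prof$combined[1]))
  expect_true(all(prof$antisense == 0))
  twice <- suppressWarnings(metaprofile(rbind(anchors, anchors), rs, g))
  expect_equal(twice$combined, prof$combined)
  # anchor order invariance
  perm <- suppressWarnings(metaprofile(anchors[c(3, 1, 2), ], rs, g))
  expect_equal(perm$combined, prof$combined)
  expect_error(suppressWarnings(metaprofile(anchors[0, ], rs, g)),
               "at least one anchor")
})

test_that("per-bin 5th-95th trimming neutralizes an outlier anchor", {
  g <- tiny_genome(1, 2e6)
  centers <- seq(2e4, 2e6 - 2e4, length.out = 100)
  # identical read stack at every anchor: per-bin distributions degenerate
  reads <- do.call(rbind, lapply(centers, function(c0)
    stack_reads(5, start = c0 - 100, len = 200)))
  # one extreme site: 80 stacked reads
  out_center <- 1e6 + 12345
  reads_out <- rbind(reads, stack_reads(80, start = out_center - 100,
                                        len = 200))
  rs <- read_set(reads)
  rs_out <- read_set(reads_out)
  rs_out$library_size <- rs$library_size  # same normalization
  anchors <- genomic_intervals("chr1", centers - 500, centers + 500)
  anchors_out <- rbind(anchors,
                       genomic_intervals("chr1", out_center - 500,
                                         out_center + 500))
  p0 <- metaprofile(anchors, rs, g)
  p1 <- metaprofile(anchors_out, rs_out, g)
  expect_equal(p1$combined, p0$combined)
  # the outlier is far above every bin's 95th percentile
  peak_bin <- which.max(p0$combined)
  expect_gt(max(p1$per_anchor$combined[101, ]),
            max(p1$per_anchor$combined[1:100, peak_bin]) * 10)
  # without trimming the outlier would shift the mean
  expect_gt(mean(p1$per_anchor$combined[, peak_bin]),
            mean(p1$per_anchor$combined[1:100, peak_bin]))
})

test_that("loess smoothing reproduces constants and lines, rejects tiny spans", {
  expect_equal(loess_smooth(rep(2.5, 400), span = 0.1), rep(2.5, 400))
  lin <- seq(0, 5, length.out = 400)
  expect_equal(loess_smooth(lin, span = 0.1), lin, tolerance = 1e-6)
  expect_error(loess_smooth(rep(1, 400), span = 0.005), "span too small")
  expect_error(loess_smooth(rep(1, 400), span = 2), "span")
  set.seed(4)
  for (i in 1:5) {
    y <- runif(400)
    s <- loess_smooth(y, span = 0.1)
    expect_true(all(s <= max(y) + 1e-9) && all(s >= min(y) - 1e-9))
  }
})

test_that("heatmap matrix: input correction, scaling, and class row order", {
  g <- tiny_genome(1, 2e6)
  bins <- seq(0, 2e6 - 100, by = 100)
  set.seed(8)
  chip <- genomic_intervals("chr1", bins, bins + 100,
                            score = rpois(length(bins), 10))
  tstrs <- genomic_intervals("chr1", c(3e5, 9e5, 15e5), c(3e5, 9e5, 15e5) + 1000)
  tstrs$class <- enrichment_class(c(TRUE, FALSE, TRUE),
                                  c(FALSE, FALSE, TRUE))
  # chip == input -> all zero after correction (with a warning)
  expect_warning(hm0 <- heatmap_matrix(tstrs, chip, chip, g), "constant")
  expect_true(all(hm0$matrix == 0))
  # non-degenerate: matrix-wide mean 0, SD 1
  input <- chip
  input$score <- rpois(length(bins), 10)
  hm <- heatmap_matrix(tstrs, chip, input, g)
  expect_equal(mean(hm$matrix), 0, tolerance = 1e-12)
  expect_equal(sd(as.numeric(hm$matrix)), 1, tolerance = 1e-12)
  expect_equal(ncol(hm$matrix), 2000)
  # rows ordered none < k27ac_only < p300_only < both
  expect_equal(as.character(hm$row_index$class),
               c("none", "p300_only", "both"))
})

test_that("anchor centers sit at the maximum ChIP coverage, leftmost on ties", {
  track <- genomic_intervals("chr1", c(0, 100, 200, 300),
                             c(100, 200, 300, 400),
                             score = c(1, 7, 7, 2))
  peaks <- genomic_intervals("chr1", 0, 400)
  expect_equal(anchor_centers(peaks, track), 100)
  empty_peak <- genomic_intervals("chr2", 0, 400)
  expect_equal(anchor_centers(empty_peak, track), 200)  # midpoint fallback
})
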