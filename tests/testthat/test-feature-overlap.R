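test_that("conservation score is the max overlapping element score", {
  tstr <- genomic_intervals("chr1", 10000, 11000)
  tstr$peak_center <- 10500
  ph <- genomic_intervals("chr1", c(10300, 10600, 50000),
                          c(10400, 10700, 50100),
                          score = c(350, 500, 999))
  cs <- conservation_score(tstr, ph)
  expect_equal(cs$score, 500)
  expect_true(cs$conserved)
  far <- genomic_intervals("chr1", 5e5, 5e5 + 1000)
  cs2 <- conservation_score(far, ph)
  expect_true(is.na(cs2$score))
  expect_false(cs2$conserved)
  # element touching only the edge base of the 1 kb window still counts
  edge <- genomic_intervals("chr1", 10999, 11200, score = 42)
  expect_equal(conservation_score(tstr, edge)$score, 42)  # window [10000,11000)
  outside <- genomic_intervals("chr1", 11000, 11200, score = 42)
  expect_false(conservation_score(tstr, outside)$conserved)
})

test_that("CAGE overlap geometry: 1 kb window vs midpoint +/- 1 kb", {
  tstr <- genomic_intervals("chr1", 99500, 100500)
  tstr$peak_center <- 100000
  near <- genomic_intervals("chr1", 101390, 101410)  # midpoint 1400 bp away
  expect_true(cage_overlap(tstr, near))
  far <- genomic_intervals("chr1", 101590, 101610)  # midpoint 1600 bp away
  expect_false(cage_overlap(tstr, far))
  expect_false(cage_overlap(tstr, empty_intervals()))
})

test_that("Fisher 2x2: worked examples, enumeration values, oracle equality", {
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1)
  expect_warning(pz <- fisher_exact_2x2(0, 0, 3, 4), "margin")
  expect_equal(pz, 1)
  set.seed(21)
  for (i in 1:100) {
    tab <- matrix(sample(0:20, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("overlap enrichment test wires fractions into the 2x2 table", {
  res <- overlap_enrichment_test(c(rep(TRUE, 70), rep(FALSE, 30)),
                                 c(rep(TRUE, 28), rep(FALSE, 72)))
  expect_equal(res$fraction_tstr, 0.7)
  expect_equal(res$fraction_control, 0.28)
  expect_equal(res$p, stats::fisher.test(res$table)$p.value,
               tolerance = 1e-9)
  expect_lt(res$p, 0.01)
})

test_that("ChIP classification: boundary rule, monotonicity, background guard", {
  g <- tiny_genome(1, 2e6)
  bins <- seq(0, 2e6 - 100, by = 100)
  flat <- genomic_intervals("chr1", bins, bins + 100, score = 5)
  input0 <- genomic_intervals("chr1", 0, 2e6, score = 0)
  tstr <- genomic_intervals("chr1", 1.5e6, 1.5e6 + 1000)
  bg <- genomic_intervals("chr1", 0, 1e6)
  # uniform track: every background bin equals the window value -> the 95th
  # percentile equals the value itself, and >= means enriched
  cls <- chip_enrichment_classify(tstr, list(p300 = flat, k27ac = flat),
                                  input0, bg)
  expect_true(cls$enriched_p300)
  expect_equal(as.character(cls$class), "both")
  # raising coverage in the window can never flip enriched -> not
  boosted <- flat
  boosted$score[boosted$start >= 1.5e6 & boosted$end <= 1.5e6 + 1000] <- 50
  cls2 <- chip_enrichment_classify(tstr, list(p300 = boosted, k27ac = flat),
                                   input0, bg)
  expect_true(cls2$enriched_p300)
  # variable background, window at the background mean -> not enriched
  set.seed(33)
  noisy <- genomic_intervals("chr1", bins, bins + 100,
                             score = rpois(length(bins), 10))
  noisy$score[noisy$start >= 1.5e6 & noisy$end <= 1.5e6 + 1000] <- 10
  cls3 <- chip_enrichment_classify(tstr, list(p300 = noisy, k27ac = noisy),
                                   input0, bg, strategy = "raw")
  expect_false(cls3$enriched_p300)
  expect_error(chip_enrichment_classify(tstr, list(p300 = flat, k27ac = flat),
                                        input0,
                                        genomic_intervals("chr1", 0, 1e5)),
               "background")
})

test_that("simulated p300 loci classify as p300-enriched", {
  sim <- simulate_bundle(small_config(n_specific = 40, p_p300 = 1,
                                      p_k27ac = 0))
  tr <- sim$tracks
  spec <- sim$truth[sim$truth$has_p300, ]
  regions <- genomic_intervals(spec$chrom, spec$start, spec$end)
  all_win <- center_windows(sim$truth$chrom,
                            floor((sim$truth$start + sim$truth$end) / 2),
                            4000, sim$genome)
  bg <- suppressWarnings(GenomicRanges::gaps(GenomicRanges::reduce(
    GenomicRanges::GRanges(all_win$chrom,
                           IRanges::IRanges(all_win$start + 1, all_win$end),
                           seqlengths = chrom_lengths(sim$genome)))))
  bg <- bg[GenomicRanges::strand(bg) == "*"]
  bg_df <- genomic_intervals(as.character(GenomicRanges::seqnames(bg)),
                             GenomicRanges::start(bg) - 1,
                             GenomicRanges::end(bg))
  cls <- chip_enrichment_classify(regions,
                                  list(p300 = tr$chip$p300,
                                       k27ac = tr$chip$k27ac),
                                  tr$chip$input, bg_df,
                                  min_background = 2e5)
  expect_gte(mean(cls$enriched_p300), 0.95)
  # unflagged mark: false-positive rate of a 95th-percentile cutoff is ~5%
  expect_lte(mean(cls$enriched_k27ac), 0.2)
})

test_that("TSS distances are strand-aware minima over all genes", {
  genes <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                      strand = c("+", "-"), tx_start = c(50000, 90000),
                      tx_end = c(60000, 95000))
  tstr <- genomic_intervals("chr1", c(49500, 84500), c(50500, 85500))
  d <- distance_to_nearest_tss(tstr, genes)
  expect_equal(d[1], 0)        # center 50000 == TSS of g1
  expect_equal(d[2], 10000)    # center 85000 vs TSS g2 at 95000 (minus strand)
  set.seed(14)
  rg <- data.frame(gene = sprintf("g%d", 1:30), chrom = "chr1",
                   strand = sample(c("+", "-"), 30, replace = TRUE),
                   tx_start = sort(sample(1e6, 30)))
  rg$tx_end <- rg$tx_start + 5000
  r_tstr <- genomic_intervals("chr1", 4e5, 4e5 + 1000)
  tss <- ifelse(rg$strand == "+", rg$tx_start, rg$tx_end)
  expect_equal(distance_to_nearest_tss(r_tstr, rg),
               min(abs(400500 - tss)))
  expect_error(distance_to_nearest_tss(r_tstr, rg[0, ]), "no genes")
})

test_that("class summaries partition regions and close the DI CDF", {
  tab <- data.frame(class = enrichment_class(c(TRUE, TRUE, FALSE, FALSE),
                                             c(TRUE, FALSE, TRUE, FALSE)),
                    si = c(0.5, 0.2, 0.9, 0.1),
                    di_a = c(0.1, 0.4, 0.8, 0.2),
                    di_b = c(0.3, 0.2, 0.6, 0.9),
                    rpkm_a = 1:4, rpkm_b = 4:1,
                    conserved = c(TRUE, FALSE, TRUE, TRUE),
                    tss_distance = c(1e3, 2e4, 5e4, 1e5))
  cs <- class_summaries(tab)
  expect_equal(sum(cs$summary$n), nrow(tab))
  expect_setequal(cs$summary$class,
                  c("none", "k27ac_only", "p300_only", "both"))
  for (cl in names(cs$di_cdf)) {
    curve <- cs$di_cdf[[cl]]
    if (nrow(curve)) expect_equal(curve$cum[nrow(curve)], 1)
  }
  one_class <- tab
  one_class$class <- enrichment_class(rep(TRUE, 4), rep(TRUE, 4))
  cs1 <- class_summaries(one_class)
  expect_equal(cs1$summary$n[cs1$summary$class == "both"], 4)
  expect_true(all(is.na(
    cs1$summary$mean_si[cs1$summary$class != "both"])))
})
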