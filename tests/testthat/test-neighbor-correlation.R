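test_that("gene expression uses the exon union, counting spanning reads once", {
  g <- tiny_genome(1, 1e5)
  genes <- data.frame(gene = "g1", name = "tx1", chrom = "chr1",
                      strand = "+", tx_start = 1000, tx_end = 9000,
                      cds_start = 1000, cds_end = 9000, exon_count = 3,
                      stringsAsFactors = FALSE)
  # overlapping exons 1000-3000 and 2500-4000 merge; plus 8000-9000
  genes$exon_starts <- I(list(c(1000, 2500, 8000)))
  genes$exon_ends <- I(list(c(3000, 4000, 9000)))
  spanning <- genomic_intervals("chr1", 2900, 3100, strand = "+")  # hits both
  intronic <- genomic_intervals("chr1", 5000, 5200, strand = "+")
  rs <- read_set(rbind(spanning, intronic))
  gx <- gene_expression(genes, rs, rs)
  expect_equal(gx$exon_union_length, (4000 - 1000) + 1000)
  expect_equal(gx$rpkm_a, rpkm(1, 4000, rs$library_size))
  expect_equal(gx$tss, 1000)
  # SI relative to the matching tissue
  gx2 <- gx; gx2$rpkm_a <- 3; gx2$rpkm_b <- 1
  expect_equal(gene_specificity_index(gx2, TRUE), 0.5)
  expect_equal(gene_specificity_index(gx2, FALSE), -0.5)
  gx3 <- gx; gx3$rpkm_a <- 2; gx3$rpkm_b <- 0
  expect_equal(gene_specificity_index(gx3, TRUE), 1)
  gx3$rpkm_b <- 2
  expect_equal(gene_specificity_index(gx3, TRUE), 0)
})

test_that("nearest-gene ranking orders by |center - TSS| with id tie-break", {
  tstr <- genomic_intervals("chr1", 99500, 100500)  # center 100000
  genes <- data.frame(gene = c("gC", "gA", "gB", "gD", "gE", "gF"),
                      chrom = "chr1", strand = "+",
                      tx_start = c(101000, 105000, 109000, 99000, 91000,
                                   130000),
                      stringsAsFactors = FALSE)
  genes$tx_end <- genes$tx_start + 500
  genes$tss <- genes$tx_start
  ranked <- rank_nearest_genes(tstr, genes, k_max = 3)
  expect_equal(genes$gene[ranked$gene], c("gC", "gD", "gA"))
  expect_equal(ranked$distance, c(1000, 1000, 5000))
  # tie at 1000 bp: gC before gD lexicographically
  set.seed(19)
  rg <- data.frame(gene = sprintf("g%02d", 1:40), chrom = "chr1",
                   strand = "+", tx_start = sample(1e6, 40),
                   stringsAsFactors = FALSE)
  rg$tx_end <- rg$tx_start + 100
  rg$tss <- rg$tx_start
  rk <- rank_nearest_genes(tstr, rg, k_max = 5)
  brute <- order(abs(100000 - rg$tss), rg$gene)[1:5]
  expect_equal(rk$gene, brute)
})

test_that("binned correlation degenerates to Pearson and is order-invariant", {
  set.seed(6)
  gsi <- runif(87, -1, 1)
  tsi <- 0.6 * gsi + 0.4 * runif(87, -1, 1)
  expect_equal(bin_and_correlate(gsi, tsi, bin_size = 1)$r, cor(gsi, tsi),
               tolerance = 1e-12)
  expect_equal(bin_and_correlate(gsi, gsi, bin_size = 10)$r, 1)
  perm <- sample(87)
  expect_equal(bin_and_correlate(gsi[perm], tsi[perm], 20)$r,
               bin_and_correlate(gsi, tsi, 20)$r)
  # partial final bin: 87 = 4 x 20 + 7 -> merged into the 4th bin
  expect_equal(nrow(bin_and_correlate(gsi, tsi, 20)$bins), 4)
  # 90 = 4 x 20 + 10 -> kept as a 5th bin
  expect_equal(nrow(bin_and_correlate(runif(90), runif(90), 20)$bins), 5)
  expect_error(bin_and_correlate(runif(15), runif(15), 20), "2 bins")
})

test_that("independent specificity indices give near-zero binned correlation", {
  rs <- vapply(1:20, function(s) {
    set.seed(s)
    bin_and_correlate(runif(2000, -1, 1), runif(2000, -1, 1), 20)$r
  }, 0)
  expect_true(all(abs(rs) < 0.3))
})

test_that("random gene control is seeded and same-chromosome", {
  tstrs <- genomic_intervals(rep(c("chr1", "chr2"), each = 3),
                             seq(1e4, 6e4, by = 1e4),
                             seq(1e4, 6e4, by = 1e4) + 1000)
  genes <- data.frame(gene = c("g1", "g2", "g3"),
                      chrom = c("chr1", "chr1", "chr2"), strand = "+",
                      tx_start = c(1e5, 2e5, 3e5), stringsAsFactors = FALSE)
  genes$tx_end <- genes$tx_start + 100
  pairs <- random_gene_control(tstrs, genes, seed = 2)
  expect_identical(pairs, random_gene_control(tstrs, genes, seed = 2))
  expect_true(all(genes$chrom[pairs$gene] == tstrs$chrom[pairs$tstr]))
  # single gene on chr2 -> always that gene
  expect_true(all(pairs$gene[tstrs$chrom[pairs$tstr] == "chr2"] == 3))
  lone <- genomic_intervals("chr3", 100, 600)
  expect_warning(random_gene_control(lone, genes, seed = 1), "skipped")
})

test_that("planted SI coupling: nearest-gene correlation beats random control", {
  wins <- vapply(1:10, function(s) {
    set.seed(300 + s)
    n_genes <- 60; n_tstr <- 120
    genes <- data.frame(gene = sprintf("g%02d", 1:n_genes), chrom = "chr1",
                        strand = "+",
                        tx_start = sort(sample(2e6, n_genes)),
                        stringsAsFactors = FALSE)
    genes$tx_end <- genes$tx_start + 1000
    gene_si <- runif(n_genes, -1, 1)
    genes$rpkm_a <- 1 + gene_si
    genes$rpkm_b <- 1 - gene_si
    genes$tss <- genes$tx_start
    # each TSTR sits next to one gene and inherits its SI plus noise
    host <- sample(n_genes, n_tstr, replace = TRUE)
    tstrs <- genomic_intervals("chr1", genes$tx_start[host] + 2000,
                               genes$tx_start[host] + 3000)
    tstrs$si <- pmax(-1, pmin(1, gene_si[host] + rnorm(n_tstr, 0, 0.15)))
    tstrs$tissue <- "A"
    res <- suppressWarnings(
      neighbor_correlation(tstrs, genes, tissues = c("A", "B"),
                           k_max = 3, bin_size = 20, seed = s))
    res$r[res$rank == "1"] > res$r[res$rank == "random"]
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})
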