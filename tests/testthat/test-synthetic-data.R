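test_that("genome construction is deterministic and validates config", {
  cfg <- sim_config(chromosomes = c(chrA = 1e6, chrB = 1e6))
  g <- build_genome(cfg)
  expect_equal(nrow(g), 2)
  expect_equal(sum(g$length), 2e6)
  expect_identical(g, build_genome(cfg))
  expect_error(sim_config(chromosomes = numeric()), "config error")
  expect_error(sim_config(chromosomes = c(chr1 = -5)), "config error")
  expect_error(sim_config(dispersion = 0), "config error")
  expect_error(sim_config(depth = c(-1, 1)), "config error")
})

test_that("annotation: gene structure, bounds, and disjoint planted loci", {
  cfg <- small_config(n_genes = 10)
  g <- build_genome(cfg)
  ann <- build_annotation(g, cfg)
  expect_equal(nrow(ann$genes), 10)
  expect_true(all(ann$genes$exon_count >= 1))
  len <- chrom_lengths(g)
  expect_true(all(ann$genes$tx_start >= 0 &
                    ann$genes$tx_end <= len[ann$genes$chrom]))
  for (i in seq_len(nrow(ann$genes))) {
    expect_true(all(ann$genes$exon_starts[[i]] >= ann$genes$tx_start[i]))
    expect_true(all(ann$genes$exon_ends[[i]] <= ann$genes$tx_end[i]))
  }
  loci <- plant_loci(g, ann, cfg)
  intergenic <- loci[!loci$genic, ]
  expect_equal(sum(overlaps_any(intergenic, ann$exclusions)), 0)
  expect_equal(sum(overlaps_any(intergenic, ann$rrna)), 0)
  expect_true(all(loci$genic[loci$locus_id %in%
                               sprintf("decoy%03d", 1:4)]))
  # too dense to place -> generation error
  dense <- small_config(n_genes = 500)
  expect_error(build_annotation(build_genome(dense), dense),
               "generation error")
})

test_that("read simulation matches configured moments and strand model", {
  cfg <- small_config(n_specific = 0, n_nonspecific = 1, n_genic_decoys = 0,
                      mean_nonspecific = 400)
  g <- build_genome(cfg)
  ann <- build_annotation(g, cfg)
  loci <- plant_loci(g, ann, cfg)
  counts <- vapply(1:10, function(i) {
    cfg_i <- small_config(n_specific = 0, n_nonspecific = 1,
                          n_genic_decoys = 0, mean_nonspecific = 400,
                          seed = 100 + i)
    sim <- simulate_reads(g, ann, loci, cfg_i)
    sim$truth$count_A[1]
  }, 0)
  # Poisson(400): SE of the mean of 10 replicates = sqrt(400/10)
  expect_lt(abs(mean(counts) - 400), 3 * sqrt(400 / 10))

  cfg1 <- small_config(sense_fraction = 1)
  sim1 <- simulate_bundle(cfg1)
  locus_reads <- overlaps_any(sim1$readsets$A$reads, sim1$truth)
  named <- grepl("locus", sim1$readsets$A$reads$name)
  expect_true(all(sim1$readsets$A$reads$strand[named] == "+"))

  cfg0 <- small_config(depth = c(0, 1))
  sim0 <- simulate_bundle(cfg0)
  expect_equal(nrow(sim0$readsets$A$reads), 0)
  expect_gt(nrow(sim0$readsets$B$reads), 0)
})

test_that("library size excludes rRNA-overlapping reads and hits the manifest", {
  sim <- simulate_bundle(small_config())
  for (t in c("A", "B")) {
    rs <- sim$readsets[[t]]
    n_rrna <- sum(overlaps_any(rs$reads, sim$annotation$rrna))
    expect_equal(rs$library_size, nrow(rs$reads) - n_rrna)
    expect_gt(n_rrna, 0)  # rRNA loci are expressed, so exclusion is exercised
  }
  tmp <- withr::local_tempdir()
  write_fixture_bundle(sim, tmp)
  man <- read_manifest(file.path(tmp, "manifest.txt"))
  expect_equal(as.integer(man[["library_size_A"]]),
               sim$readsets$A$library_size)
  expect_equal(as.integer(man[["seed"]]), sim$config$seed)
})

test_that("feature tracks encode the planted flags", {
  cfg <- small_config(p_p300 = 0, p_k27ac = 1, p_conserved = 1, p_cage = 1)
  sim <- simulate_bundle(cfg)
  tracks <- sim$tracks
  # no locus has p300 -> the track is pure background (no enrichment blocks)
  expect_lt(max(tracks$chip$p300$score), 60)
  # every conserved locus 1 kb center window hits a phastCons element
  cons <- sim$truth[sim$truth$conserved, ]
  win <- center_windows(cons$chrom, floor((cons$start + cons$end) / 2), 1000,
                        sim$genome)
  expect_true(all(overlaps_any(win, tracks$phastcons)))
  # H3K27ac coverage at a flagged locus exceeds the 95th background percentile
  flagged <- sim$truth[sim$truth$has_k27ac, ][1, ]
  fwin <- center_windows(flagged$chrom,
                         floor((flagged$start + flagged$end) / 2), 1000,
                         sim$genome)
  bg_bins <- tracks$chip$k27ac[!overlaps_any(
    tracks$chip$k27ac,
    center_windows(sim$truth$chrom,
                   floor((sim$truth$start + sim$truth$end) / 2), 4000,
                   sim$genome)), ]
  cutoff <- quantile(bg_bins$score, 0.95, names = FALSE)
  expect_gt(track_window_mean(tracks$chip$k27ac, fwin), cutoff)
  # known-enhancer records carry the active tissue
  expect_true(all(tracks$enhancers$tissue %in% c("A", "B")))
})

test_that("identical config and seed give byte-identical fixture bundles", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_bundle(simulate_bundle(small_config(seed = 42)), d1)
  write_fixture_bundle(simulate_bundle(small_config(seed = 42)), d2)
  expect_identical(unname(dir_md5(d1)), unname(dir_md5(d2)))
  d3 <- withr::local_tempdir()
  write_fixture_bundle(simulate_bundle(small_config(seed = 43)), d3)
  expect_false(identical(unname(dir_md5(d1)), unname(dir_md5(d3))))
})

test_that("negative binomial noise is available and overdisperses counts", {
  cfg <- small_config(noise = "nb", dispersion = 0.5, n_specific = 0,
                      n_nonspecific = 12, mean_nonspecific = 100,
                      n_genic_decoys = 0)
  g <- build_genome(cfg)
  ann <- build_annotation(g, cfg)
  loci <- plant_loci(g, ann, cfg)
  counts <- unlist(lapply(1:8, function(i) {
    cfg_i <- cfg; cfg_i$seed <- 200 + i
    simulate_reads(g, ann, loci, cfg_i)$truth$count_A
  }))
  # NB(mu=100, dispersion 0.5): variance = 100 + 0.5 * 100^2 >> Poisson
  expect_gt(var(counts), 3 * mean(counts))
})

test_that("fixture bundles reload into equivalent objects", {
  sim <- simulate_bundle(small_config(seed = 9))
  tmp <- withr::local_tempdir()
  write_fixture_bundle(sim, tmp)
  back <- read_fixture_bundle(tmp)
  expect_equal(back$readsets$A$library_size, sim$readsets$A$library_size)
  expect_equal(nrow(back$annotation$genes), nrow(sim$annotation$genes))
  expect_equal(back$tracks$enhancers$tissue, sim$tracks$enhancers$tissue)
  expect_equal(nrow(back$truth), nrow(sim$truth))
})
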