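test_that("two-proportion z-test: worked examples and degenerate cases", {
  eq <- two_proportion_z(10, 10, 1e6, 1e6)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  r <- two_proportion_z(30, 10, 1e6, 1e6)
  expect_equal(r$z, 3.1623, tolerance = 1e-4)
  expect_equal(r$p, 1.57e-3, tolerance = 1e-2)
  # z^2 equals the Pearson chi-square statistic of the 2x2 table
  chi <- suppressWarnings(stats::chisq.test(
    matrix(c(30, 1e6 - 30, 10, 1e6 - 10), 2, byrow = TRUE),
    correct = FALSE))
  expect_equal(r$z^2, unname(chi$statistic), tolerance = 1e-9)
  z0 <- two_proportion_z(0, 0, 1e6, 1e6)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)
  expect_error(two_proportion_z(11, 1, 10, 10), "input error")
  expect_error(two_proportion_z(1, 1, 0, 10), "positive")
})

test_that("z-test equals chi-square and prop.test on random tables; swap symmetry", {
  set.seed(7)
  for (i in 1:200) {
    big_n <- sample(1e4:1e6, 2)
    n <- c(sample(0:500, 1), sample(0:500, 1))
    r <- two_proportion_z(n[1], n[2], big_n[1], big_n[2])
    if (r$p0 > 0 && r$p0 < 1) {
      chi <- suppressWarnings(stats::chisq.test(
        matrix(c(n[1], big_n[1] - n[1], n[2], big_n[2] - n[2]), 2,
               byrow = TRUE), correct = FALSE))
      expect_equal(r$z^2, unname(chi$statistic), tolerance = 1e-9)
      pt <- suppressWarnings(stats::prop.test(n, big_n, correct = FALSE))
      expect_equal(r$p, pt$p.value, tolerance = 1e-9)
    }
    sw <- two_proportion_z(n[2], n[1], big_n[2], big_n[1])
    expect_equal(sw$z, -r$z)
    expect_equal(sw$p, r$p)
  }
})

test_that("RPKM arithmetic and the 2^-9 visualization floor", {
  expect_equal(rpkm(20, 2000, 1e7), 1.0)
  expect_equal(rpkm(0, 2000, 1e7, visualization_floor = TRUE), 2^-9)
  expect_equal(rpkm(0, 2000, 1e7), 0)
  expect_error(rpkm(1, 0, 1e6), "positive")
})

test_that("specificity and directionality indices", {
  expect_equal(specificity_index(5, 5), 0)
  expect_equal(specificity_index(7, 0), 1)
  expect_equal(specificity_index(3, 1), 0.5)
  expect_error(specificity_index(-1, 1), "input error")
  expect_warning(s0 <- specificity_index(0, 0), "undefined")
  expect_equal(s0, 0)
  expect_equal(directionality_index(4, 4), 0)
  expect_equal(directionality_index(9, 0), 1)
  expect_equal(directionality_index(30, 10), 0.5)
  # symmetry in (f, r); tissue swap preserves DI, flips SI
  expect_equal(directionality_index(10, 30), directionality_index(30, 10))
  expect_equal(specificity_index(1, 3), -specificity_index(3, 1))
  expect_error(directionality_index(-2, 1), "input error")
})

test_that("enhancer fold change applies the zero -> 1 substitution", {
  r <- enhancer_fold_change(40, 0, 1e6, 1e6)
  expect_equal(r$fold, 40)
  expect_equal(r$log2fc, log2(40))
  expect_gt(r$z, 0)
  eqr <- enhancer_fold_change(25, 25, 1e6, 1e6)
  expect_equal(eqr$fold, 1)
  expect_equal(eqr$log2fc, 0)
  both0 <- enhancer_fold_change(0, 0, 1e6, 1e6)
  expect_equal(both0$fold, 1)
  expect_equal(both0$p, 1)
})

test_that("concordance fraction: strict inequality, ties discordant", {
  lab <- c("A", "A", "B", "B")
  all_conc <- concordance_fraction(lab, c(5, 9, 1, 0), c(1, 2, 4, 6))
  expect_equal(all_conc$overall, 1)
  ties <- concordance_fraction(lab, c(3, 3, 3, 3), c(3, 3, 3, 3))
  expect_equal(ties$overall, 0)
  expect_equal(unname(all_conc$by_tissue), c(1, 1))
  expect_error(concordance_fraction(character(), numeric(), numeric()),
               "empty")
})

test_that("exact doubled-tail binomial test reproduces known values", {
  # 12/15 at p0 = 1/3: doubled upper tail, 6e-4 to one significant figure
  p <- exact_concordance_test(12, 15, 1 / 3)
  expect_equal(signif(p, 1), 6e-4)
  expect_equal(p, 2 * sum(dbinom(12:15, 15, 1 / 3)), tolerance = 1e-12)
  expect_equal(exact_concordance_test(3, 3, 1 / 3), 2 / 27,
               tolerance = 1e-12)
  expect_equal(exact_concordance_test(5, 15, 1 / 3), 1)
})

test_that("TSTR calling assigns the higher-proportion tissue under strict alpha", {
  counted <- data.frame(n_a = c(30, 30, 0), n_b = c(10, 28, 0))
  out <- call_tstrs(counted, 1e6, 1e6, alpha = 0.01)
  expect_equal(out$tissue, c("A", "none", "none"))
  # boundary: p == alpha is NOT called (strict <)
  p_obs <- two_proportion_z(30, 10, 1e6, 1e6)$p
  at <- call_tstrs(data.frame(n_a = 30, n_b = 10), 1e6, 1e6, alpha = p_obs)
  expect_equal(at$tissue, "none")
  just <- call_tstrs(data.frame(n_a = 30, n_b = 10), 1e6, 1e6,
                     alpha = p_obs * 1.001)
  expect_equal(just$tissue, "A")
  rev <- call_tstrs(data.frame(n_a = 10, n_b = 30), 1e6, 1e6, alpha = 0.01)
  expect_equal(rev$tissue, "B")
})

test_that("null regions are called at about the nominal rate", {
  set.seed(11)
  counted <- data.frame(n_a = rpois(1000, 30), n_b = rpois(1000, 30))
  out <- call_tstrs(counted, 1e6, 1e6, alpha = 0.01)
  expect_lte(mean(out$tissue != "none"), 0.02)
})

test_that("qPCR candidate selection pools the top 30% by |z|", {
  tstrs <- data.frame(name = letters[1:10], z = c(-9, 8, 7, -6, 5, 4, -3, 2,
                                                  1, 0))
  sel <- select_qpcr_candidates(tstrs, 3, seed = 5)
  expect_setequal(sel$name, c("a", "b", "c"))  # pool = ceil(3) strongest
  expect_error(select_qpcr_candidates(tstrs, 4, seed = 5), "pool")
  expect_identical(select_qpcr_candidates(tstrs, 2, seed = 8),
                   select_qpcr_candidates(tstrs, 2, seed = 8))
})
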