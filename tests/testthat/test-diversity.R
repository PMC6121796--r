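# pi, Tajima's D, d_XY/d_A against brute-force allele-pair oracles.

test_that("pi: identical samples give 0; one difference in 100 callable gives 0.01", {
  lay <- genome_layout("sc1", 100)
  w <- make_windows(lay, 100)
  vt0 <- make_vt(rbind(c(2, 2), c(0, 0)), pos = c(10, 20))
  expect_equal(window_pi(vt0, vt0$samples, w, 100), 0)

  # one diploid (2 haplotypes) differing at 1 of 100 callable sites
  vt1 <- make_vt(rbind(1), pos = 50)
  expect_equal(window_pi(vt1, vt1$samples[1], w, 100), 0.01)
})

test_that("windowed pi, dxy, da and Tajima's D match the pairwise oracle on a 50-site table", {
  set.seed(21)
  gt <- matrix(sample(0:2, 50 * 10, replace = TRUE, prob = c(4, 3, 3)), 50, 10)
  gt[sample(length(gt), 15)] <- NA
  vt <- make_vt(gt, pos = sort(sample(1:9000, 50)))
  gx <- vt$samples[1:6]; gy <- vt$samples[7:10]
  lay <- genome_layout("sc1", 10000)
  w <- make_windows(lay, 10000)
  callable <- 10000

  expect_equal(window_pi(vt, gx, w, callable),
               oracle_pi_total(gt[, 1:6]) / callable, tolerance = 1e-10)
  dd <- window_dxy_da(vt, gx, gy, w, callable)
  expect_equal(dd$dxy, oracle_dxy_total(gt[, 1:6], gt[, 7:10]) / callable,
               tolerance = 1e-10)
  expect_equal(dd$da,
               dd$dxy - (window_pi(vt, gx, w, callable) +
                           window_pi(vt, gy, w, callable)) / 2,
               tolerance = 1e-14)

  gt_full <- gt; gt_full[is.na(gt_full)] <- 1  # oracle D assumes complete data
  vt_full <- make_vt(gt_full, pos = vt$sites$pos)
  expect_equal(window_tajimas_d(vt_full, gx, w),
               oracle_tajima_d(gt_full[, 1:6]), tolerance = 1e-10)
})

test_that("Tajima's D: undefined at S = 0, negative for all-singleton windows", {
  lay <- genome_layout("sc1", 10000)
  w <- make_windows(lay, 10000)
  vt0 <- make_vt(matrix(0, 3, 10), pos = c(10, 20, 30))
  expect_true(is.na(window_tajimas_d(vt0, vt0$samples, w)))

  # n = 20 haplotypes, 3 segregating sites, all singletons
  gt <- matrix(0L, 3, 10)
  gt[1, 1] <- 1L; gt[2, 4] <- 1L; gt[3, 8] <- 1L
  vts <- make_vt(gt, pos = c(100, 200, 300))
  d <- window_tajimas_d(vts, vts$samples, w)
  expect_lt(d, 0)
  expect_equal(d, oracle_tajima_d(gt), tolerance = 1e-12)
})

test_that("Tajima coefficients satisfy their defining identities", {
  cf <- tajima_coefficients(20)
  expect_equal(cf$a1, sum(1 / (1:19)))
  expect_equal(cf$e1, cf$c1 / cf$a1)
  expect_true(all(is.finite(unlist(tajima_coefficients(4)))))
})

test_that("neutral-spectrum generator gives mean Tajima's D near zero", {
  set.seed(31)
  lay <- genome_layout("sc1", 5e6)
  w <- make_windows(lay, 10000)
  vt <- simulate_group_variants(5e6, 10, 0.005, spectrum = "neutral",
                                scaffold = "sc1", seed = NULL)
  d <- window_tajimas_d(vt, vt$samples, w)
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.08)
})

test_that("dxy identities: equal fixed haplotypes give 0; 5 fixed diffs in 1kb give 0.005", {
  lay <- genome_layout("sc1", 1000)
  w <- make_windows(lay, 1000)
  gt_same <- matrix(2, 4, 6)
  vt_same <- make_vt(gt_same, pos = c(10, 20, 30, 40))
  dd <- window_dxy_da(vt_same, vt_same$samples[1:3], vt_same$samples[4:6], w, 1000)
  expect_equal(dd$dxy, 0)
  expect_equal(dd$da, 0)

  gt_fix <- rbind(matrix(rep(c(0, 0, 0, 2, 2, 2), 5), 5, byrow = TRUE))
  vt_fix <- make_vt(gt_fix, pos = seq(100, 500, by = 100))
  dd2 <- window_dxy_da(vt_fix, vt_fix$samples[1:3], vt_fix$samples[4:6], w, 1000)
  expect_equal(dd2$dxy, 0.005)
  expect_equal(dd2$da, 0.005)  # pi = 0 in both groups
})

test_that("pi and dxy are invariant under relabeling within groups", {
  set.seed(8)
  gt <- matrix(sample(0:2, 40 * 8, replace = TRUE), 40, 8)
  vt <- make_vt(gt, pos = sort(sample(1:5000, 40)))
  lay <- genome_layout("sc1", 5000)
  w <- make_windows(lay, 5000)
  g1 <- vt$samples[1:4]; g2 <- vt$samples[5:8]
  expect_equal(window_pi(vt, g1, w, 5000), window_pi(vt, rev(g1), w, 5000))
  expect_equal(window_dxy_da(vt, g1, g2, w, 5000)$dxy,
               window_dxy_da(vt, sample(g1), sample(g2), w, 5000)$dxy)
})
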