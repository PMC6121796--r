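# PCA, region MDS and SS/NS/NN classification.

test_that("PCA separates fixed-difference populations on axis 1", {
  gt <- cbind(matrix(0L, 30, 6), matrix(2L, 30, 6))
  gt <- gt + matrix(sample(0:0, 360, TRUE), 30)  # noiseless
  # add a little polymorphism so more than one PC exists
  gt[1:3, ] <- matrix(sample(0:2, 36, TRUE), 3)
  colnames(gt) <- sprintf("s%02d", 1:12)
  pc <- genotype_pca(gt)
  side <- pc$scores[, 1][1:6]; other <- pc$scores[, 1][7:12]
  expect_true(max(side) < min(other) || min(side) > max(other))
  expect_gt(pc$varprop[1], 0.8)
})

test_that("duplicated samples get identical PCA coordinates", {
  set.seed(14)
  gt <- matrix(sample(0:2, 200, TRUE), 20, 10)
  gt <- cbind(gt, gt[, 1])
  colnames(gt) <- c(sprintf("s%02d", 1:10), "dup")
  pc <- genotype_pca(gt)
  expect_equal(pc$scores["dup", ], pc$scores["s01", ], tolerance = 1e-8)
})

test_that("excluding the differentiating loci removes the separation", {
  set.seed(15)
  n <- 12
  bg <- matrix(rbinom(200 * n, 2, runif(200, 0.2, 0.8)), 200, n)
  diag_loci <- rbind(matrix(0L, 40, n / 2), matrix(2L, 40, n / 2))
  diag_loci <- cbind(matrix(0L, 40, n / 2), matrix(2L, 40, n / 2))
  gt <- rbind(bg, diag_loci)
  colnames(gt) <- sprintf("s%02d", 1:n)
  loci <- data.frame(scaffold = rep(c("bg", "reg"), c(200, 40)),
                     pos = c(1:200, 1:40))
  regions <- GenomicRanges::GRanges("reg", IRanges::IRanges(1, 1000))
  pop <- rep(c(0, 1), each = n / 2)
  sep <- function(pc) {
    s <- pc$scores[, 1]
    abs(mean(s[pop == 0]) - mean(s[pop == 1])) /
      sqrt(mean(tapply(s, pop, var)))
  }
  pc_all <- genotype_pca(gt, loci)
  pc_no <- genotype_pca(gt, loci, exclude = regions)
  expect_gt(sep(pc_all), 5)
  expect_lt(sep(pc_no), 1.5)
})

test_that("MDS of the three diploid classes is collinear and equally spaced", {
  # diagnostic loci only: all-0/0, all-0/1, all-1/1
  gt <- cbind(rep(0L, 20), rep(1L, 20), rep(2L, 20))
  colnames(gt) <- c("ss", "ns", "nn")
  # a couple of shared polymorphisms so the MDS has rank > 1
  gt <- rbind(gt, matrix(c(0L, 1L, 0L, 1L, 0L, 1L), 2, 3))
  mds <- region_mds(gt, "toy")
  x <- mds$points[, "axis1"]
  expect_equal(unname(x["ns"]), unname((x["ss"] + x["nn"]) / 2),
               tolerance = 0.05)
  expect_equal(sum(mds$points[, 1]), 0, tolerance = 1e-8)
})

test_that("classification recovers generator truth with three equidistant clusters", {
  cfg <- sim_config(seed = 16)
  rs <- simulate_divergent_region(cfg, "chr1", seed = 16)
  mds <- region_mds(biallelic_snps(rs$table)$gt, "chr1")
  call <- classify_region_genotypes(mds, pop = rs$table$pop)
  truth <- rowSums(rs$truth$clade_pairs)
  pred <- c(SS = 0, NS = 1, NN = 2)[call$calls$class]
  expect_equal(unname(pred), unname(truth[call$calls$sample]))
  expect_lt(call$equidistance, 0.1)
  expect_equal(call$n_clusters, 3)

  # homozygous-northern sample at every diagnostic locus is NN
  nn_sample <- call$calls$sample[which(truth[call$calls$sample] == 2)[1]]
  expect_equal(call$calls$class[call$calls$sample == nn_sample], "NN")
})

test_that("no split (T = 0) yields a single dominant cluster flagged as degraded", {
  cfg <- sim_config(seed = 17)
  cfg$regions$chr3$T_split <- 0
  rs <- simulate_divergent_region(cfg, "chr3", seed = 17)
  mds <- region_mds(biallelic_snps(rs$table)$gt, "chr3")
  expect_lt(mds$eig_share, 0.5)
})

test_that("axis-1 ordering is stable under 50% locus subsampling", {
  cfg <- sim_config(seed = 18)
  rs <- simulate_divergent_region(cfg, "chr5", seed = 18)
  gt <- biallelic_snps(rs$table)$gt
  full <- region_mds(gt, "chr5")$points[, 1]
  truth <- rowSums(rs$truth$clade_pairs)
  set.seed(1)
  for (i in 1:3) {
    sub <- region_mds(gt[sample(nrow(gt), nrow(gt) %/% 2), ], "chr5")$points[, 1]
    if (cor(full, sub) < 0) sub <- -sub  # sign-flip normalisation
    expect_gt(cor(full, sub), 0.99)
    # the three cluster means keep their order along axis 1
    m_full <- tapply(full, truth[names(full)], mean)
    m_sub <- tapply(sub, truth[names(sub)], mean)
    expect_equal(order(m_full), order(m_sub))
  }
})

test_that("site frequencies follow (2 NN + NS) / (2 assigned)", {
  calls <- list(calls = data.frame(
    sample = sprintf("s%d", 1:8),
    class = c("NN", "NN", "NS", "SS", "SS", "SS", "unassigned", "NS"),
    posterior = 1, axis1 = 0))
  md <- data.frame(sample = sprintf("s%d", 1:8),
                   site = c(rep("a", 4), rep("b", 4)))
  fr <- haplotype_site_frequencies(calls, md)
  expect_equal(fr$freq_N[fr$site == "a"], 5 / 8)
  # site b: SS, SS, unassigned, NS -> (0 + 1) / 6
  expect_equal(fr$freq_N[fr$site == "b"], 1 / 6)
  expect_equal(fr$n_assigned[fr$site == "b"], 3)

  md2 <- rbind(md, data.frame(sample = "s9", site = "c"))
  fr2 <- haplotype_site_frequencies(calls, md2)
  expect_true(is.na(fr2$freq_N[fr2$site == "c"]))
})

test_that("combined genotype tables reflect allopatric vs hybrid-zone structure", {
  mk <- function(cls) list(calls = data.frame(sample = sprintf("s%d", seq_along(cls)),
                                              class = cls, posterior = 1, axis1 = 0))
  allo1 <- mk(c("SS", "SS", "NN", "NN"))
  allo5 <- mk(c("SS", "SS", "NN", "NN"))
  tab <- combined_genotype_table(allo1, allo5)
  expect_equal(unname(tab["SS", "SS"] + tab["NN", "NN"]), 4)
  hyb1 <- mk(c("NS", "NS", "NN", "SS"))
  hyb5 <- mk(c("NS", "SS", "NN", "NS"))
  tab2 <- combined_genotype_table(hyb1, hyb5)
  expect_gt(tab2["NS", "NS"], 0)
  single <- combined_genotype_table(mk("NN"), mk("SS"))
  expect_equal(unname(single["NN", "SS"]), 1)
  expect_false(attr(single, "empty"))
})
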