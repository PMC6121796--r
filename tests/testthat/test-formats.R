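# Reading/writing the standard formats and the coordinate conventions.

test_that("window tiling covers scaffolds and flags partial windows", {
  lay <- genome_layout(c("a", "b", "c"), c(25000, 10000, 9999))
  w <- make_windows(lay, 10000)
  wa <- w[w$scaffold == "a", ]
  expect_equal(wa$start, c(0, 10000, 20000))
  expect_equal(wa$end, c(10000, 20000, 25000))
  expect_equal(wa$partial, c(FALSE, FALSE, TRUE))
  expect_equal(sum(w$scaffold == "b"), 1)
  expect_false(w$partial[w$scaffold == "b"])
  expect_true(w$partial[w$scaffold == "c"])
  expect_equal(w$index, seq_len(nrow(w)))
})

test_that("1-based positions map to floor((p-1)/size) windows", {
  lay <- genome_layout("a", 30000)
  w <- make_windows(lay, 10000)
  pos <- c(1, 9999, 10000, 10001, 20000, 20001, 30000)
  idx <- assign_windows(w, rep("a", length(pos)), pos)
  expect_equal(w$start[idx] %/% 10000, (pos - 1) %/% 10000)
  # boundary: position 10000 is the last base of the first window
  expect_equal(idx[3], 1L)
  expect_equal(idx[4], 2L)
})

test_that("genome layout validates lengths and duplicates", {
  expect_error(genome_layout(c("a", "a"), c(10, 10)), "duplicate")
  expect_error(genome_layout("a", 0), "positive")
  lay <- genome_layout(c("a", "b"), c(100, 50), c("1", "1"))
  expect_true(all(diff(lay$offset) > 0))
})

test_that("toy VCF parses with genotype, missing and multiallelic handling", {
  f <- tempfile(fileext = ".vcf")
  write_toy_vcf(f, c(
    "sc1\t100\t.\tA\tT\t50\tPASS\t.\tGT:DP\t0/0:10\t0/1:12",
    "sc1\t200\t.\tG\tC\t60\tPASS\t.\tGT:DP\t1/1:9\t./.:0",
    "sc1\t300\t.\tA\tT,G\t55\tPASS\t.\tGT:DP\t0/1:8\t1/2:7"))
  vt <- read_variant_table(f, c(s1 = "southern", s2 = "northern"))
  expect_equal(nrow(vt$sites), 3)
  expect_equal(vt$gt[1, ], c(s1 = 0L, s2 = 1L))
  expect_true(is.na(vt$gt[2, "s2"]))   # ./. is missing
  expect_equal(unname(vt$dp[1, "s2"]), 12)
  # multiallelic flagged, biallelic view has n-1 sites
  expect_false(vt$sites$is_biallelic[3])
  expect_equal(nrow(biallelic_snps(vt)$sites), 2)
  expect_equal(unname(vt$pop), c("southern", "northern"))
  expect_error(read_variant_table(f, c(zz = "southern")), "zz")
})

test_that("variant table round-trips through VCF", {
  set.seed(42)
  gt <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 20, 3)
  dp <- matrix(rpois(60, 9), 20, 3)
  vt <- make_vt(gt, dp = dp)
  f <- tempfile(fileext = ".vcf")
  write_variant_vcf(vt, f)
  vt2 <- read_variant_table(f)
  expect_equal(unname(vt2$gt), unname(vt$gt))
  expect_equal(vt2$sites$pos, vt$sites$pos)
  expect_equal(unname(vt2$dp), unname(dp))
})

test_that("BED intervals are merged, validated, and counted", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("sc1\t0\t10", "sc1\t5\t20"), f)
  m <- read_intervals(f)
  expect_equal(length(m), 1)
  expect_equal(mask_total(m), 20)

  writeLines(character(0), f)
  expect_equal(mask_total(read_intervals(f)), 0)

  writeLines(c("sc1\t0\t10", "sc1\t50\t60", "sc2\t0\t15"), f)
  expect_equal(mask_total(read_intervals(f)), 35)

  writeLines(c("sc1\t0\t10", "sc1\t30\t30"), f)
  expect_error(read_intervals(f), "line 2")
})

test_that("masks round-trip through BED and complement correctly", {
  lay <- genome_layout("sc1", 100)
  m <- read_intervals({
    f <- tempfile(); writeLines(c("sc1\t10\t20", "sc1\t40\t50"), f); f
  })
  f2 <- tempfile()
  write_intervals(m, f2)
  expect_equal(mask_total(read_intervals(f2)), 20)
  comp <- mask_complement(lay, m)
  expect_equal(mask_total(comp), 80)
  # half-open convention: position = interval end is outside the mask
  expect_equal(positions_in_mask(m, c("sc1", "sc1", "sc1"), c(11, 20, 21)),
               c(TRUE, TRUE, FALSE))
})

test_that("per-window callable counts intersect mask and tiling", {
  lay <- genome_layout("sc1", 20000)
  w <- make_windows(lay, 10000)
  f <- tempfile()
  writeLines(c("sc1\t0\t5000", "sc1\t10000\t20000"), f)
  counts <- window_callable_counts(read_intervals(f), w)
  expect_equal(counts, c(5000, 10000))
})

test_that("sample metadata is typed, validated, and keeps missing cells", {
  f <- tempfile()
  writeLines(c(
    "sample\tsite\tlat\tlon\taltitude\tsex\td15N\twing\ttarsus\tbill_head\tcolor",
    "a\tx\t55\t13\t100\tM\t8.2\t67\t20\t31\t5",
    "b\tx\t55\t13\t100\tF\t\t66\t20\t30\t4",
    "c\ty\t60\t15\t200\tM\t9.0\t68\t21\t32\t",
    "d\ty\t60\t15\t200\tM\t7.7\t65\t19\t30\t2"), f)
  md <- read_sample_metadata(f)
  expect_equal(nrow(md), 4)
  expect_true(is.na(md$d15N[2]))
  expect_true(is.na(md$color[3]))

  writeLines(c(
    "sample\tsite\tlat\tlon\taltitude\tsex\td15N\twing\ttarsus\tbill_head\tcolor",
    "a\tx\t55\t13\t100\tM\t8.2\t67\t20\t31\t10"), f)
  expect_error(read_sample_metadata(f), "color")

  writeLines(c(
    "sample\tsite\tlat\tlon\taltitude\tsex\td15N\twing\ttarsus\tbill_head\tcolor",
    "a\tx\t55\t13\t100\tM\t8.2\t67\t20\t31\t5",
    "a\tx\t55\t13\t100\tM\t8.2\t67\t20\t31\t5"), f)
  expect_error(read_sample_metadata(f), "duplicate")
})

test_that("window statistics round-trip through TSV including NA rows", {
  set.seed(7)
  lay <- genome_layout("sc1", 1e6)
  w <- make_windows(lay, 10000)
  vt <- simulate_group_variants(1e6, 5, 0.005, scaffold = "sc1", seed = 1)
  vt$pop <- setNames(rep(c("southern", "northern"), c(3, 2)), vt$samples)
  callable <- rep(10000, nrow(w))
  callable[5] <- 400  # fails the 5000-callable filter
  ws <- compute_window_stats(vt, w, callable,
                             groups = list(S = vt$samples[1:3],
                                           N = vt$samples[4:5]))
  expect_true(is.na(ws$pi_S[5]) && !ws$pass_callable[5])
  f <- tempfile()
  write_window_stats(ws, f)
  ws2 <- read_window_stats(f)
  expect_equal(nrow(ws2), nrow(ws))
  expect_equal(ws2$pi_S, ws$pi_S, tolerance = 1e-12)
  expect_equal(ws2$da, ws$da, tolerance = 1e-12)
  expect_equal(ws2$pass_callable, ws$pass_callable)
})
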