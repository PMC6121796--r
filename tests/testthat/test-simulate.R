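# The synthetic-data generator: generative identities and determinism.

test_that("Balding-Nichols limits: F -> 0 gives ~0 differentiation; F = 0.5 recovers", {
  cfg0 <- sim_config(seed = 4, F_background = 1e-6,
                     background_scaffolds = c(bg1 = 2e5),
                     background_chrom = "2")
  bg0 <- simulate_background(cfg0)
  fs0 <- site_fst(bg0)
  w0 <- sum(fs0$a, na.rm = TRUE) / sum(fs0$a + fs0$b + fs0$c, na.rm = TRUE)
  expect_lt(abs(w0), 0.01)

  cfg5 <- sim_config(seed = 5, F_background = 0.5, n_per_pop = 50,
                     background_scaffolds = c(bg1 = 4e5),
                     background_chrom = "2")
  bg5 <- simulate_background(cfg5)
  fs5 <- site_fst(bg5)
  w5 <- sum(fs5$a, na.rm = TRUE) / sum(fs5$a + fs5$b + fs5$c, na.rm = TRUE)
  expect_lt(abs(w5 / 0.5 - 1), 0.05)
  expect_error(sim_config(F_background = 1.2), "F_background")
})

test_that("divergent region: T = 0 gives da ~ 0; theta = 0 limit follows the identity", {
  cfg <- sim_config(seed = 6)
  cfg$regions$chr3$T_split <- 0
  rs <- simulate_divergent_region(cfg, "chr3", seed = 6)
  lay <- genome_layout("sc_chr3", cfg$regions$chr3$length, "3")
  w <- make_windows(lay, 10000)
  S <- sprintf("S%02d", 1:8); N <- sprintf("N%02d", 1:6)
  dd <- window_dxy_da(rs$table, S, N, w, rep(10000, nrow(w)))
  expect_lt(abs(mean(dd$da)), 2e-4)
  # theta -> small: d_XY ~ d_A (pi ~ 0)
  cfg2 <- sim_config(seed = 7)
  cfg2$regions$chr3$theta_S <- cfg2$regions$chr3$theta_N <- 1e-5
  rs2 <- simulate_divergent_region(cfg2, "chr3", seed = 7)
  dd2 <- window_dxy_da(rs2$table, S, N, w, rep(10000, nrow(w)))
  expect_lt(abs(mean(dd2$dxy) / mean(dd2$da) - 1), 0.01)
  expect_lt(abs(mean(dd2$da) / 0.005 - 1), 0.1)
  # saturation guard
  cfg3 <- sim_config()
  cfg3$regions$chr3$T_split <- 1e9
  expect_error(simulate_divergent_region(cfg3, "chr3"), "saturat")
})

test_that("uniform-spectrum group generator hits E[pi] = theta", {
  vt <- simulate_group_variants(1e6, 9, 0.005, seed = 9)
  lay <- genome_layout("sim", 1e6)
  w <- make_windows(lay, 10000)
  pi <- window_pi(vt, vt$samples, w, rep(10000, nrow(w)))
  expect_lt(abs(mean(pi) / 0.005 - 1), 0.02)
})

test_that("transect sampling follows the cline and its limits", {
  cfg <- sim_config(seed = 10)
  # w -> infinity: ~constant (pmin+pmax)/2
  expect_equal(cline_predict(c(0, 500, 1500), 750, 1e9, 0.1, 0.9),
               rep(0.5, 3), tolerance = 1e-5)
  tr <- simulate_transect_sampling(cfg)
  expect_equal(nrow(tr$sites), 74)
  expect_equal(nrow(tr$individuals), 74 * cfg$site_n)
  # frequencies rise along the transect for the cline-driven regions
  sw <- tr$sites[tr$sites$transect == "sweden", ]
  expect_lt(sw$freq_chr1[1], 0.1)
  expect_gt(sw$freq_chr1[nrow(sw)], 0.9)
  # site at the center: expected frequency (pmin+pmax)/2
  mid <- cline_predict(750, 750, 373, 0.02, 0.98)
  expect_equal(mid, 0.5)
  # HWE draws: clade dosage matches site frequency on average
  dose <- rowSums(tr$clades$chr1)
  site_mean <- tapply(dose, tr$individuals$site, mean) / 2
  expect_equal(as.numeric(site_mean[sw$site]), sw$freq_chr1, tolerance = 0.2)
  expect_error(sim_config(clines = data.frame(region = "chr1",
                                              transect = "sweden",
                                              center_frac = 0.5, width = 100,
                                              pmin = 0.9, pmax = 0.1)),
               "pMin")
})

test_that("phenotypes: noiseless linkage gives |r| = 1; zero effect flags undefined", {
  cfg <- sim_config(seed = 12)
  cfg$phenotypes$d15N_site_sd <- 0
  cfg$phenotypes$d15N_ind_sd <- 0
  tr <- simulate_transect_sampling(cfg, seed = 12)
  ind <- simulate_phenotypes(cfg, tr$sites, tr$individuals, tr$clades, seed = 12)
  site_d15N <- tapply(ind$d15N, ind$site, mean)
  r <- cor(site_d15N[tr$sites$site], tr$sites$freq_chr1)
  expect_equal(abs(r), 1, tolerance = 1e-4)

  cfg2 <- sim_config(seed = 13)
  cfg2$phenotypes$d15N_beta <- 0
  cfg2$phenotypes$d15N_site_sd <- 0
  cfg2$phenotypes$d15N_ind_sd <- 0
  tr2 <- simulate_transect_sampling(cfg2, seed = 13)
  ind2 <- simulate_phenotypes(cfg2, tr2$sites, tr2$individuals, tr2$clades,
                              seed = 13)
  expect_equal(var(ind2$d15N), 0)  # degenerate: correlation undefined downstream
})

test_that("same seed gives byte-identical studies; different seeds differ", {
  cfg <- sim_config(
    seed = 3,
    background_scaffolds = c(bg1 = 1e5), background_chrom = "2",
    regions = list(chr1 = list(scaffold = "sc_chr1", length = 1e5,
                               chromosome = "1", T_split = 250000,
                               theta_S = 0.005, theta_N = 0.007),
                   chr3 = list(scaffold = "sc_chr3", length = 1e5,
                               chromosome = "3", T_split = 250000,
                               theta_S = 0.005, theta_N = 0.005),
                   chr5 = list(scaffold = "sc_chr5", length = 1e5,
                               chromosome = "5", T_split = 150000,
                               theta_S = 0.005, theta_N = 0.007)),
    site_plan = c(sweden = 6, east = 5), site_n = 4)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  r1 <- simulate_study(cfg, d1)
  r2 <- simulate_study(cfg, d2)
  for (f in names(r1$files)) {
    expect_identical(unname(tools::md5sum(r1$files[[f]])),
                     unname(tools::md5sum(r2$files[[f]])), label = f)
  }
  vt1 <- read_variant_table(r1$files$vcf)
  expect_equal(length(vt1$samples), 18)

  cfg2 <- cfg; cfg2$seed <- 4
  d3 <- file.path(tempdir(), "sim_c")
  r3 <- simulate_study(cfg2, d3)
  vt3 <- read_variant_table(r3$files$vcf)
  expect_false(identical(vt1$gt, vt3$gt))
})
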