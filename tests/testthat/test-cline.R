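# Transect projection and maximum-likelihood cline fitting.

test_that("transect projection: endpoints map to 0 and |AB|; haversine checks out", {
  tr <- data.frame(lat_a = 0, lon_a = 0, lat_b = 0, lon_b = 10)
  d <- transect_distance(c(0, 0), c(0, 10), tr)
  len <- transect_length(tr)
  expect_equal(d$distance[1], 0, tolerance = 1e-6)
  expect_equal(d$distance[2], len, tolerance = 1e-6)
  # 1 degree at the equator ~ 111.19 km (2*pi*6371/360)
  expect_equal(haversine_km(0, 0, 0, 1), 2 * pi * 6371 / 360, tolerance = 1e-6)
  d1 <- transect_distance(0, 1, tr)
  expect_equal(d1$distance, haversine_km(0, 0, 0, 1), tolerance = 1e-6)
  # off-axis site is flagged
  far <- transect_distance(10, 5, tr, off_axis_tol = 300)
  expect_true(far$flagged)
})

test_that("cline equation identities: center, tails, slope", {
  expect_equal(cline_predict(750, 750, 373, 0.02, 0.98), 0.5)
  expect_equal(cline_predict(-1e9, 750, 373, 0.02, 0.98), 0.02)
  expect_equal(cline_predict(1e9, 750, 373, 0.02, 0.98), 0.98)
  # slope at the center equals (pmax - pmin) / width
  eps <- 0.01
  slope <- (cline_predict(750 + eps, 750, 373, 0.02, 0.98) -
              cline_predict(750 - eps, 750, 373, 0.02, 0.98)) / (2 * eps)
  expect_equal(slope, (0.98 - 0.02) / 373, tolerance = 1e-6)
})

test_that("ML fit recovers generative parameters and beats the truth's likelihood", {
  set.seed(19)
  x <- seq(50, 1450, length.out = 20)
  truth <- c(center = 750, width = 373, pmin = 0.02, pmax = 0.98)
  p <- cline_predict(x, truth["center"], truth["width"], truth["pmin"],
                     truth["pmax"])
  n <- rep(60, 20)
  k <- rbinom(20, n, p)
  ft <- fit_cline(x, n, k, boot = 0)
  expect_true(ft$converged)
  expect_equal(unname(coef(ft)["width"]), 373, tolerance = 0.2)
  expect_equal(unname(coef(ft)["center"]), 750, tolerance = 0.1)
  # likelihood at the fitted optimum >= likelihood at the truth
  ll_truth <- sum(k * log(p) + (n - k) * log(1 - p))
  expect_gte(logLik(ft) + 1e-9, ll_truth)
  # predict/residual methods are consistent
  expect_equal(predict(ft, x), cline_predict(x, coef(ft)["center"],
                                             coef(ft)["width"],
                                             coef(ft)["pmin"],
                                             coef(ft)["pmax"]))
  expect_equal(residuals(ft), k / n - predict(ft))
})

test_that("fit is invariant to reversing the transect direction", {
  set.seed(20)
  x <- seq(0, 1500, length.out = 18)
  p <- cline_predict(x, 600, 300, 0.05, 0.9)
  n <- rep(40, 18); k <- rbinom(18, n, p)
  f1 <- fit_cline(x, n, k, boot = 0)
  f2 <- fit_cline(1500 - x, n, n - k, boot = 0)
  expect_equal(unname(coef(f2)["center"]), 1500 - unname(coef(f1)["center"]),
               tolerance = 1e-3)
  expect_equal(unname(coef(f2)["width"]), unname(coef(f1)["width"]),
               tolerance = 1e-3)
  expect_equal(unname(coef(f2)["pmin"]), 1 - unname(coef(f1)["pmax"]),
               tolerance = 1e-2)
})

test_that("degenerate data are flagged: step cline, constant frequency, boundary", {
  x <- seq(0, 1000, length.out = 10)
  n <- rep(50, 10)
  step_k <- ifelse(x < 500, 0, 50)
  fs <- fit_cline(x, n, step_k, boot = 0)
  expect_true("width_at_lower_bound" %in% fs$flags ||
                coef(fs)["width"] < 70)
  flat <- fit_cline(x, n, rep(25, 10), boot = 0)
  expect_true(length(flat$flags) > 0)
  allzero <- fit_cline(x, n, rep(0, 10), boot = 0)
  expect_true("boundary_data" %in% allzero$flags)
})

test_that("bootstrap CI contains the point estimate and simulate() is seeded", {
  set.seed(22)
  x <- seq(50, 1450, length.out = 20)
  p <- cline_predict(x, 750, 300, 0.02, 0.98)
  n <- rep(60, 20); k <- rbinom(20, n, p)
  ft <- fit_cline(x, n, k, boot = 80, boot_seed = 9)
  ci <- confint(ft)
  expect_true(ci["width", 1] <= coef(ft)["width"] &&
                coef(ft)["width"] <= ci["width", 2])
  s1 <- simulate(ft, nsim = 2, seed = 5)
  s2 <- simulate(ft, nsim = 2, seed = 5)
  expect_identical(s1, s2)
})

test_that("neutral diffusion width: 2.51 sigma sqrt(T) and monotonicities", {
  expect_equal(neutral_diffusion_width(50, 100)$width, 1255)
  expect_equal(neutral_diffusion_width(100, 100)$width,
               2 * neutral_diffusion_width(50, 100)$width)
  expect_equal(neutral_diffusion_width(50, 400)$width,
               2 * neutral_diffusion_width(50, 100)$width)
  expect_error(neutral_diffusion_width(-1, 10))
})
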