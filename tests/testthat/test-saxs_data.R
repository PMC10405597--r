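test_that(".dat reader tolerates headers and validates the numbers", {
  path <- tempfile(fileext = ".dat")
  writeLines(c("# sample description", "q I err",
               " 0.010 105.2 1.1", " 0.020 99.8 1.0", " 0.030 90.1 0.9",
               " 0.040 78.0 0.8", " 0.050 66.3 0.7"), path)
  p <- read_iq(path)
  expect_length(p$q_grid, 5L)
  expect_equal(p$intensity[2], 99.8)
  expect_equal(p$sigma[5], 0.7)
  writeLines(c("0.01 10 0.1", "0.02 9 -0.1"), path)
  expect_error(read_iq(path), "negative sigma")
  writeLines(c("0.02 10 0.1", "0.01 9 0.1"), path)
  expect_error(read_iq(path), "non-monotonic")
  writeLines("# only a header", path)
  expect_error(read_iq(path), "no numeric")
})

test_that("GNOM-style .out round trips through the module's own writer", {
  r <- seq(0.5, 49.5, by = 1)
  p <- r^2 * exp(-r / 10); p[r > 45] <- 0
  err <- 0.05 * p + 0.01
  pr <- distance_distribution(r, p, errors = err)
  path <- tempfile(fileext = ".out")
  write_gnom_out(pr, path)
  back <- read_gnom_out(path)
  expect_equal(back$pr$r_grid, r, tolerance = 1e-6)
  expect_equal(back$pr$p, p, tolerance = 1e-6)
  expect_equal(back$pr$errors, err, tolerance = 1e-6)
  expect_equal(back$pr$dmax, 44.5, tolerance = 1e-6)  # last non-zero r
  # 0.5 Å spacing detected as written
  r2 <- seq(0.25, 20, by = 0.5)
  pr2 <- distance_distribution(r2, r2 * exp(-r2))
  write_gnom_out(pr2, path)
  expect_equal(read_gnom_out(path)$pr$bin_width, 0.5, tolerance = 1e-6)
  # truncated file errors with context
  writeLines(c("Distance distribution", " 1.0 2.0 0.1"), path)
  expect_error(read_gnom_out(path), "truncated")
})

test_that("rebinning to 1 Å preserves shape, integral and interpolates errors", {
  r <- seq(0.25, 60, by = 0.5)
  peak <- 30
  p <- pmax(0, 1 - abs(r - peak) / 20)       # triangle profile
  err <- seq_along(r) * 0.01
  pr <- distance_distribution(r, p, errors = err)
  rb <- rebin_pr(pr, 1)
  expect_equal(rb$bin_width, 1)
  expect_equal(max(rb$p), 1, tolerance = 0.03)   # peak preserved
  expect_equal(sum(rb$p) * 1, sum(p) * 0.5, tolerance = 0.01)
  # errors interpolated linearly: midpoint of neighbours
  i <- 10
  src <- approx(r, err, xout = rb$r_grid[i])$y
  expect_equal(rb$errors[i], src, tolerance = 0.02)
  expect_identical(rebin_pr(rb, 1), rb)          # already 1 Å: identity
  expect_error(rebin_pr(pr, 20), "coarser")
})

test_that("Guinier fit is exact on noise-free Guinier-law data", {
  for (rg_true in c(15, 40, 80)) {
    for (mq in c(1.0, 1.3)) {
      q <- seq(0.002, 0.2, by = 0.001)
      p <- intensity_profile(q, 100 * exp(-q^2 * rg_true^2 / 3))
      g <- guinier_fit(p, max_qrg = mq)
      expect_lt(abs(g$rg - rg_true) / rg_true, 1e-6)
      expect_equal(g$i0, 100, tolerance = 1e-6)
      expect_lte(g$max_qrg, mq + 1e-9)
    }
  }
  # skipping leading points is honoured
  q <- seq(0.002, 0.2, by = 0.001)
  I <- 100 * exp(-q^2 * 40^2 / 3)
  I[1:10] <- I[1:10] * 5              # parasitic upturn
  g <- guinier_fit(intensity_profile(q, I), max_qrg = 1.0, n_skip_low_q = 10)
  expect_equal(g$rg, 40, tolerance = 1e-6)
  expect_equal(g$n_skipped_low_q, 10)
  # negative intensity in the window errors
  I[30] <- -1
  expect_error(guinier_fit(intensity_profile(q, I), 1.0, 10), "non-positive")
})

test_that("IFT recovers the sphere P(r) and its Rg", {
  prof <- sphere_profile(R = 50)
  res <- ift(prof, dmax = 100)
  expect_lt(abs(res$rg - sqrt(3 / 5) * 50) / (sqrt(3 / 5) * 50), 0.01)
  x <- res$pr$r_grid / 100
  closed <- res$pr$r_grid^2 * (1 - 1.5 * x + 0.5 * x^3)
  expect_lt(max(abs(res$pr$p / max(res$pr$p) - closed / max(closed))), 0.02)
  expect_true(all(res$pr$p >= 0))
  # dmax overshoot: P(r) vanishes beyond the true diameter
  res2 <- ift(prof, dmax = 120)
  expect_lt(max(res2$pr$p[res2$pr$r_grid > 100]), 0.01 * max(res2$pr$p))
  # linearity in the data
  prof2 <- intensity_profile(prof$q_grid, 3 * prof$intensity,
                             sigma = 3 * prof$sigma)
  res3 <- ift(prof2, dmax = 100, alpha = res$regularization)
  expect_equal(res3$pr$p, 3 * ift(prof, dmax = 100,
                                  alpha = res$regularization)$pr$p,
               tolerance = 1e-6)
  expect_error(ift(prof, dmax = 5), "dmax")
  expect_error(ift(prof, dmax = 100, alpha = -1), "alpha")
})

test_that("standardized dmax selection finds the sphere diameter", {
  prof <- sphere_profile(R = 50)
  sel <- select_dmax(prof, dmax_range = c(80, 130))
  expect_true(sel$satisfied)
  expect_gte(sel$dmax, 96)
  expect_lte(sel$dmax, 106)
  # invariant to overall intensity scale
  prof2 <- intensity_profile(prof$q_grid, 10 * prof$intensity,
                             sigma = 10 * prof$sigma)
  expect_equal(select_dmax(prof2, dmax_range = c(80, 130))$dmax, sel$dmax)
})

test_that("quality report applies the pi/qmin rule", {
  q <- seq(0.0141, 0.3, by = 0.001)
  p <- intensity_profile(q, 100 * exp(-q^2 * 40^2 / 3))
  rep <- data_quality(p, rg_hint = 40, max_qrg = 1.3)
  expect_equal(rep$dmax_limit, pi / 0.0141, tolerance = 1e-6)
  expect_equal(round(rep$dmax_limit), 223)   # ~220 Å characterization limit
  # Guinier point count equals the brute-force window count
  expect_equal(rep$n_guinier_points, sum(q * 40 <= 1.3))
})

test_that("sequence mass uses average residue masses plus one water", {
  expect_equal(mass_from_sequence("GG"), 132.12, tolerance = 1e-3)
  expect_gt(mass_from_sequence("ACDEFGHIKLMNPQRSTVWY"), 2000)
  expect_error(mass_from_sequence(""), "empty")
  expect_error(mass_from_sequence("GZ"), "unknown residue")
})
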