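kkt_holds <- function(A, b, x, tol = 1e-8) {
  g <- drop(crossprod(A, b - A %*% x))        # negative gradient
  scale <- max(abs(crossprod(A, b)))
  pos <- x > 0
  all(g[pos] <= tol * scale & g[pos] >= -tol * scale) &&
    all(g[!pos] <= tol * scale)
}

test_that("NNLS solves exactly-representable problems", {
  c1 <- c(1, 0, 2, 0)
  expect_equal(nnls_solve(cbind(c1), 2 * c1)$x, 2)
  # orthogonal two-column design
  c2 <- c(0, 3, 0, 1)
  sol <- nnls_solve(cbind(c1, c2), 0.3 * c1 + 0.7 * c2)
  expect_equal(sol$x, c(0.3, 0.7), tolerance = 1e-12)
  expect_error(nnls_solve(cbind(c1), rep(0, 4)), "all-zero")
  expect_error(nnls_solve(cbind(c1), 1:3), "grid mismatch")
})

test_that("NNLS satisfies KKT optimality and beats random feasible points", {
  set.seed(11)
  for (rep in 1:5) {
    A <- matrix(rnorm(40 * 20), 40, 20)
    b <- drop(A %*% runif(20)) + rnorm(40, sd = 0.5)
    sol <- nnls_solve(A, b)
    expect_true(kkt_holds(A, b, sol$x))
    # stochastic oracle: 10^4 random non-negative trial vectors
    trials <- matrix(runif(20 * 1e4, 0, 2 * max(sol$x, 0.1)), 20)
    resid <- sqrt(colSums((b - A %*% trials)^2))
    expect_lte(sol$residual_norm, min(resid))
  }
})

test_that("NNLS agrees with an independent active-set implementation", {
  skip_if_not_installed("pracma")
  set.seed(21)
  for (rep in 1:5) {
    A <- matrix(abs(rnorm(60 * 15)), 60, 15)
    b <- drop(A %*% c(runif(5), rep(0, 10)))+ rnorm(60, sd = 0.1)
    ours <- nnls_solve(A, b)
    ref <- pracma::lsqnonneg(A, b)
    expect_equal(ours$residual_norm, sqrt(ref$resid.norm), tolerance = 1e-6)
    expect_equal(ours$x, ref$x, tolerance = 1e-6)
  }
})

test_that("adding columns never increases the NNLS residual", {
  set.seed(31)
  for (rep in 1:5) {
    A <- matrix(abs(rnorm(50 * 12)), 50, 12)
    b <- abs(rnorm(50))
    r_small <- nnls_solve(A[, 1:6], b)$residual_norm
    r_big <- nnls_solve(A, b)$residual_norm
    expect_lte(r_big, r_small + 1e-9)
  }
})

test_that("error weighting with constant sigma matches the unweighted fit", {
  set.seed(41)
  A <- matrix(abs(rnorm(50 * 8)), 50, 8)
  b <- abs(rnorm(50))
  x0 <- nnls_solve(A, b)$x
  x1 <- nnls_solve(A, b, weights = rep(1 / 0.37, 50))$x
  expect_equal(x0, x1, tolerance = 1e-10)
})

test_that("ensemble fit recovers the target and generator truth", {
  pool <- fix_pool()
  prs <- lapply(pool$models, compute_pr)
  # pool containing the target itself: single member, fraction 1
  tgt <- prs[[17]]
  f <- fit_ensemble(prs[c(3, 17, 40)], tgt)
  expect_equal(f$member_ids, 2L)
  expect_equal(f$fractions, 1)
  expect_lt(f$chi2, 1e-12)
  # noise-free composite of two generator conformers in a ~200-member pool:
  # exact weight recovery
  sub <- subselect_pool(pool, 2)
  q <- seq(0.005, 0.4, by = 0.005)
  iqs <- lapply(sub$models, debye_iq, q_grid = q)
  sim <- simulate_experiment(sub, c(10L, 100L), c(0.4, 0.6), q, noise_rel = 0)
  f2 <- fit_ensemble(iqs, sim$iq)
  expect_setequal(f2$member_ids, c(10L, 100L))
  expect_equal(f2$fractions[match(c(10, 100), f2$member_ids)], c(0.4, 0.6),
               tolerance = 1e-6)
  # fractions invariant to common rescaling of the pool profiles
  iqs_scaled <- lapply(iqs, function(p)
    intensity_profile(p$q_grid, 7.3 * p$intensity))
  f3 <- fit_ensemble(iqs_scaled, sim$iq)
  expect_equal(f3$fractions[match(c(10, 100), f3$member_ids)],
               f2$fractions[match(c(10, 100), f2$member_ids)],
               tolerance = 1e-9)
  # smooth profiles make the design rank-deficient: whatever support NNLS
  # settles on, the composite must still reproduce the target essentially
  # exactly (the solution set is degenerate, the fit is not)
  sim_b <- simulate_experiment(sub, c(30L, 95L), c(0.4, 0.6), q, noise_rel = 0)
  f4 <- fit_ensemble(iqs, sim_b$iq)
  expect_lt(sqrt(sum((f4$composite$intensity - sim_b$iq$intensity)^2)) /
              sqrt(sum(sim_b$iq$intensity^2)), 1e-6)
  expect_error(fit_ensemble(list(), tgt), "empty")
  expect_error(fit_ensemble(prs[1:3], tgt, error_weighted = TRUE), "sigma")
})

test_that("composite profiles are fraction-weighted sums", {
  p1 <- intensity_profile(1:5 / 10, rep(1, 5))
  p3 <- intensity_profile(1:5 / 10, rep(3, 5))
  cp <- composite_profile(list(p1, p3), c(0.5, 0.5))
  expect_equal(cp$intensity, rep(2, 5))
  cp1 <- composite_profile(list(p1), 1)
  expect_equal(cp1$intensity, p1$intensity)
  # random pool equals the matrix product oracle
  set.seed(5)
  mats <- replicate(6, abs(rnorm(5)), simplify = FALSE)
  profs <- lapply(mats, function(v) intensity_profile(1:5 / 10, v))
  fr <- runif(6); fr <- fr / sum(fr)
  want <- drop(do.call(cbind, mats) %*% fr)
  expect_equal(composite_profile(profs, fr)$intensity, want)
  expect_error(composite_profile(list(p1, p3), c(0.2, 0.2)), "sum to 1")
})

test_that("optimal scaling and chi-square behave as a goodness of fit", {
  q <- seq(0.01, 0.3, length.out = 50)
  I <- 100 * exp(-q^2 * 30^2 / 3)
  e <- intensity_profile(q, I, sigma = 0.02 * I)
  same <- scale_and_chi2(intensity_profile(q, I), e)
  expect_equal(same$scale, 1)
  expect_equal(same$chi2, 0)
  dbl <- scale_and_chi2(intensity_profile(q, 2 * I), e)
  expect_equal(dbl$scale, 0.5)
  expect_equal(dbl$chi2, 0, tolerance = 1e-20)
  # calibration: chi2 near 1 for noise at the stated sigma
  set.seed(7)
  chis <- vapply(1:20, function(s) {
    sig <- 0.02 * I
    obs <- intensity_profile(q, I + rnorm(50, 0, sig), sigma = sig)
    scale_and_chi2(intensity_profile(q, I), obs)$chi2
  }, numeric(1))
  expect_gt(mean(chis), 0.7)
  expect_lt(mean(chis), 1.3)
})

test_that("ensemble statistics use rms Rg and fraction-weighted dmax", {
  fit <- structure(list(member_ids = c(1L, 2L), fractions = c(0.5, 0.5)),
                   class = "ensemble_fit")
  st <- ensemble_stats(fit, pool_rg_list = c(30, 40),
                       pool_dmax_list = c(100, 150))
  expect_equal(st$rg_rms, sqrt((900 + 1600) / 2))
  expect_equal(st$dmax_mean, 125)
  expect_equal(st$dmax_max, 150)
  expect_equal(st$dmax_max_fraction, 0.5)
  one <- structure(list(member_ids = 2L, fractions = 1), class = "ensemble_fit")
  expect_equal(ensemble_stats(one, pool_rg_list = c(30, 40),
                              pool_dmax_list = c(100, 150))$rg_rms, 40)
})

test_that("union refitting never fits worse than its parts", {
  pool <- fix_pool()
  q <- seq(0.005, 0.4, by = 0.005)
  iqs <- lapply(pool$models, debye_iq, q_grid = q)
  prs <- lapply(pool$models, compute_pr)
  sim <- simulate_experiment(pool, c(10, 150, 300), c(0.5, 0.3, 0.2), q,
                             noise_rel = 0.02, seed = 3)
  f_iq <- fit_ensemble(iqs, sim$iq, error_weighted = TRUE)
  f_pr <- fit_ensemble(prs, sim$pr_truth)
  uni <- refit_union(list(f_iq, f_pr), iqs, sim$iq, error_weighted = TRUE)
  expect_lte(uni$chi2, f_iq$chi2 + 1e-9)
  # idempotence: union of one fit with itself reselects the same members
  uni2 <- refit_union(list(f_iq, f_iq), iqs, sim$iq, error_weighted = TRUE)
  expect_setequal(uni2$union_ids, f_iq$member_ids)
  expect_equal(sort(uni2$fractions), sort(f_iq$fractions), tolerance = 1e-6)
  expect_error(refit_union(list(), iqs, sim$iq), "empty union")
})
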