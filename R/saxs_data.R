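# Experimental SAXS data handling: .dat and GNOM-style .out I/O, Guinier
# analysis with a self-consistent qRg window, a regularized histogram
# indirect Fourier transform (IFT), the standardized dmax selection rule,
# rebinning, and sampling-quality checks.

#' Read a SASBDB-style .dat intensity file
#'
#' ASCII with at least two numeric columns (q, I and optionally sigma);
#' '#'-prefixed or otherwise non-numeric header/footer lines are tolerated.
#'
#' @param path file path.
#' @return an [intensity_profile()]; sigma is NULL when absent.
#' @export
read_iq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[ \t,]+")
  rows <- lapply(toks, function(tk) suppressWarnings(as.numeric(tk)))
  ok <- vapply(rows, function(v) length(v) >= 2L && !anyNA(v[1:2]), logical(1))
  rows <- rows[ok]
  if (length(rows) == 0L) stop("no numeric data rows in ", path)
  ncol3 <- vapply(rows, function(v) length(v) >= 3L && !is.na(v[3]), logical(1))
  q <- vapply(rows, `[`, numeric(1), 1L)
  I <- vapply(rows, `[`, numeric(1), 2L)
  s <- if (all(ncol3)) vapply(rows, `[`, numeric(1), 3L)
  if (is.unsorted(q, strictly = TRUE)) stop("non-monotonic q in ", path)
  if (!is.null(s) && any(s < 0)) stop("negative sigma in ", path)
  if (!is.null(s) && any(s == 0)) s <- NULL
  intensity_profile(q, I, sigma = s, label = basename(path))
}

#' Read a GNOM-style .out file
#'
#' Extracts the distance-distribution block (columns R, P(R), ERROR) and,
#' when present, the regularized-fit block (S, J EXP, ERROR, J REG, I REG).
#'
#' @param path file path.
#' @return list `pr` (a `distance_distribution` with errors; dmax from the
#'   last non-zero r), `fit` (an [intensity_profile()] of the regularized
#'   intensity, or NULL), `metadata` (list with `n_points`).
#' @export
read_gnom_out <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("Distance distribution|R\\s+P\\(R\\)\\s+ERROR", lines)
  if (length(hdr) == 0L) stop("distance-distribution block not found in ", path)
  start <- max(hdr) + 1L
  block <- character(0)
  for (i in start:length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { if (length(block)) break else next }
    v <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]]))
    if (anyNA(v) || length(v) < 3L) {
      if (length(block)) break else next
    }
    block <- c(block, ln)
  }
  if (length(block) < 3L)
    stop("truncated distance-distribution block near line ", start, " of ", path)
  m <- do.call(rbind, lapply(strsplit(block, "[ \t]+"), as.numeric))
  r <- m[, 1]; p <- m[, 2]; err <- m[, 3]
  if (r[1] == 0) { r <- r[-1]; p <- p[-1]; err <- err[-1] }  # P(0) = 0 row
  nz <- which(p != 0)
  dmax <- if (length(nz)) r[max(nz)] else max(r)
  fit <- NULL
  fhdr <- grep("J EXP|J REG", lines)
  if (length(fhdr)) {
    fb <- character(0)
    for (i in (max(fhdr) + 1L):length(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln)) { if (length(fb)) break else next }
      v <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]]))
      if (anyNA(v) || length(v) < 2L) { if (length(fb)) break else next }
      fb <- c(fb, ln)
    }
    if (length(fb) > 1L) {
      fm <- do.call(rbind, lapply(strsplit(fb, "[ \t]+"), as.numeric))
      fit <- intensity_profile(fm[, 1], fm[, ncol(fm)], label = "regularized fit")
    }
  }
  pr <- distance_distribution(r, p, errors = err, dmax = dmax,
                              normalization = "raw")
  list(pr = pr, fit = fit, metadata = list(n_points = length(r)))
}

#' Write a distance distribution as a GNOM-style .out block
#'
#' @param pr a `distance_distribution`.
#' @param path output file.
#' @param fit optional [intensity_profile()] regularized fit to include.
#' @export
write_gnom_out <- function(pr, path, fit = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("  #### saxsensemble P(r) export ####", ""), con)
  if (!is.null(fit)) {
    writeLines(c("      S          J EXP       ERROR       J REG       I REG", ""), con)
    writeLines(sprintf("  %12.6e %12.6e %12.6e %12.6e %12.6e",
                       fit$q_grid, fit$intensity,
                       fit$sigma %||% rep(0, length(fit$q_grid)),
                       fit$intensity, fit$intensity), con)
    writeLines("", con)
  }
  writeLines(c("           Distance distribution  function of particle", "",
               "       R          P(R)      ERROR", ""), con)
  err <- pr$errors %||% rep(0, length(pr$p))
  writeLines(sprintf("  %12.6e %12.6e %12.6e",
                     c(0, pr$r_grid), c(0, pr$p), c(0, err)), con)
  invisible(path)
}

#' Rebin a P(r) onto a coarser uniform grid
#'
#' Values and errors are linearly interpolated onto the target grid
#' (matching common practice when loading IFT output: errors interpolated,
#' not rescaled by bin area).
#'
#' @param pr a `distance_distribution` on a uniform grid.
#' @param target_width new bin width in Å (default 1).
#' @return a `distance_distribution`.
#' @export
rebin_pr <- function(pr, target_width = 1) {
  if (target_width > pr$dmax / 4)
    stop("target bin width coarser than dmax/4")
  if (abs(target_width - pr$bin_width) < 1e-9) return(pr)
  r_new <- seq(target_width / 2, max(pr$r_grid), by = target_width)
  p_new <- stats::approx(c(0, pr$r_grid), c(0, pr$p), xout = r_new,
                         rule = 2)$y
  # preserve the integral (interpolation conserves area only approximately)
  a_old <- sum(pr$p) * pr$bin_width
  a_new <- sum(p_new) * target_width
  if (a_new > 0) p_new <- p_new * a_old / a_new
  e_new <- if (!is.null(pr$errors))
    stats::approx(c(0, pr$r_grid), c(0, pr$errors), xout = r_new, rule = 2)$y
  distance_distribution(r_new, p_new, errors = e_new, dmax = pr$dmax,
                        normalization = pr$normalization,
                        self_term = pr$self_term %||% 0)
}

#' Guinier analysis with a self-consistent qRg window
#'
#' Fits a least-squares line to (q^2, ln I) over the widest window that
#' starts at point `n_skip_low_q + 1` and satisfies `q * Rg <= max_qrg`.
#' Because Rg is unknown a priori the window is recomputed from the fitted
#' Rg until it stabilizes (cap 50 iterations). `Rg = sqrt(-3 slope)`,
#' `I0 = exp(intercept)`.
#'
#' @param profile an [intensity_profile()].
#' @param max_qrg window limit (typically 1.0-1.3).
#' @param n_skip_low_q leading points excluded (e.g. parasitic scattering).
#' @return list `rg`, `i0`, `rg_se` (from the slope standard error),
#'   `q_window`, `n_points`, `n_skipped_low_q`, `max_qrg` (realized
#'   q_last * rg).
#' @export
guinier_fit <- function(profile, max_qrg = 1.3, n_skip_low_q = 0) {
  q <- profile$q_grid; I <- profile$intensity
  first <- n_skip_low_q + 1L
  if (length(q) - n_skip_low_q < 5L) stop("fewer than 5 points after skipping")
  last <- min(length(q), first + 19L)   # initial guess window
  prev_last <- -1L
  it <- 0L
  fit <- NULL
  while (last != prev_last) {
    it <- it + 1L
    if (it > 50L) stop("Guinier window iteration did not converge")
    prev_last <- last
    idx <- first:last
    if (any(I[idx] <= 0)) stop("non-positive intensity in Guinier window")
    fit <- stats::lm.fit(cbind(1, q[idx]^2), log(I[idx]))
    slope <- fit$coefficients[2]
    if (slope >= 0) stop("non-negative Guinier slope; no Rg")
    rg <- sqrt(-3 * slope)
    last <- first - 1L + findInterval(max_qrg / rg, q[first:length(q)] + 1e-15) + 0L
    last <- max(last, first + 4L)
    last <- min(last, length(q))
  }
  idx <- first:last
  rr <- fit$residuals
  dof <- length(idx) - 2L
  s2 <- sum(rr^2) / max(dof, 1L)
  xx <- q[idx]^2
  se_slope <- sqrt(s2 / sum((xx - mean(xx))^2))
  rg <- sqrt(-3 * fit$coefficients[2])
  list(rg = unname(rg), i0 = unname(exp(fit$coefficients[1])),
       rg_se = unname(3 * se_slope / (2 * rg)),
       q_window = c(q[first], q[last]), n_points = length(idx),
       n_skipped_low_q = n_skip_low_q, max_qrg = unname(q[last] * rg))
}

# second-difference (smoothness) penalty including virtual zero nodes at
# r = 0 and r = dmax, so the ends are pulled to zero even when "released"
second_diff_matrix <- function(nb, pad = TRUE) {
  n <- nb + if (pad) 2L else 0L
  L <- matrix(0, n - 2L, n)
  for (i in seq_len(n - 2L)) L[i, i:(i + 2L)] <- c(1, -2, 1)
  if (pad) L[, 2:(n - 1L), drop = FALSE] else L
}

#' Regularized indirect Fourier transform
#'
#' P(r) is parameterized as a 1 Å histogram on \[0, dmax\] with endpoint
#' constraints P(0) = P(dmax) = 0 and recovered from I(q) by sigma-weighted
#' least squares with a second-difference (smoothness) penalty `alpha`,
#' optionally under non-negativity (solved by the package's Lawson-Hanson
#' NNLS). `alpha = NULL` selects the regularization by the discrepancy
#' principle (largest alpha with fit chi-square <= 1, falling back to the
#' minimum-chi-square alpha).
#'
#' @param profile an [intensity_profile()] with sigma.
#' @param dmax assumed maximum dimension, Å (>= 10).
#' @param alpha smoothness weight (> 0), or NULL for automatic selection.
#' @param nonneg constrain P(r) >= 0 (default TRUE).
#' @param bin_width histogram bin, Å (default 1).
#' @param constrain_dmax keep the P(dmax) = 0 endpoint constraint (the
#'   released variant is used by [select_dmax()]).
#' @param fit_background also fit a non-negative flat background (an extra
#'   constant column, excluded from P(r)); useful when the data carry a
#'   q-independent self-scattering or incoherent term, as coarse-grained
#'   bead models do.
#' @return list `pr` (a `distance_distribution`), `rg`, `i0`, `dmax`,
#'   `regularization` (alpha used), `fit_chi2`, `fit` (model
#'   [intensity_profile()]).
#' @export
ift <- function(profile, dmax, alpha = NULL, nonneg = TRUE, bin_width = 1,
                constrain_dmax = TRUE, fit_background = FALSE) {
  if (dmax < 10) stop("dmax < 10 Å")
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be > 0")
  if (is.null(profile$sigma)) stop("IFT requires a sigma column")
  q <- profile$q_grid
  r <- seq(bin_width / 2, dmax - bin_width / 2 + 1e-9, by = bin_width)
  nb <- length(r)
  A <- outer(q, r, function(qq, rr) sinc(qq * rr))
  wgt <- 1 / profile$sigma
  # solve on a scale-free system (rows weighted by normalized 1/sigma, data
  # normalized to unit weighted norm) so the result is exactly linear in the
  # data and alpha has a data-independent meaning
  u <- wgt / sqrt(mean(wgt^2))
  i_ref <- sqrt(mean((profile$intensity * u)^2))
  Aw <- A * u
  bw_vec <- profile$intensity * u / i_ref
  L <- second_diff_matrix(nb)
  keep <- seq_len(nb)
  if (constrain_dmax) keep <- keep[-nb]            # force last bin to zero
  nk <- length(keep)
  solve_one <- function(a) {
    M <- rbind(Aw[, keep, drop = FALSE], sqrt(a) * L[, keep, drop = FALSE])
    if (fit_background)                            # penalty-free flat column
      M <- cbind(M, c(u, rep(0, nrow(L))))
    y <- c(bw_vec, rep(0, nrow(L)))
    x <- if (nonneg) nnls_solve(M, y)$x else qr.solve(M, y)
    p <- numeric(nb); p[keep] <- x[seq_len(nk)] * i_ref
    bg <- if (fit_background) x[nk + 1L] * i_ref else 0
    chi2 <- sum((drop(A %*% p) + bg - profile$intensity)^2 * wgt^2) /
      max(length(q) - 1L, 1L)
    list(p = p, bg = bg, chi2 = chi2)
  }
  if (is.null(alpha)) {
    # discrepancy principle on a log grid scaled to the problem; when no
    # alpha reaches chi2 <= 1 take the smoothest within 20% of the best fit
    a0 <- sum(Aw^2) / max(sum(L^2), 1)
    grid <- a0 * 10^seq(-6, 4, by = 1)
    sols <- lapply(grid, solve_one)
    chis <- vapply(sols, `[[`, numeric(1), "chi2")
    ok <- which(chis <= max(1, 1.2 * min(chis)))
    pick <- if (length(ok)) max(ok) else which.min(chis)
    alpha <- grid[pick]; sol <- sols[[pick]]
  } else sol <- solve_one(alpha)
  pr <- distance_distribution(r, sol$p, dmax = dmax, normalization = "raw")
  fitI <- intensity_profile(q, drop(A %*% sol$p) + sol$bg, label = "IFT fit")
  list(pr = pr, rg = rg_from_pr(pr), i0 = sum(sol$p),
       dmax = dmax, regularization = alpha, fit_chi2 = sol$chi2,
       background = sol$bg, fit = fitI)
}

#' Standardized dmax selection
#'
#' Scans candidate dmax values on a grid (default 2 Å); for each candidate
#' the IFT is solved with and without the P(dmax) = 0 endpoint constraint,
#' and the released endpoint value is compared with the P(r) peak. The
#' selected dmax is the smallest whose released endpoint stays below
#' `endpoint_fraction` (default 1%) of the peak -- i.e. releasing the
#' constraint does not significantly increase P(r) at long r.
#'
#' @param profile an [intensity_profile()] with sigma.
#' @param alpha regularization (NULL = automatic, per candidate).
#' @param dmax_range `c(lo, hi)` scan range in Å.
#' @param step scan step, Å.
#' @param endpoint_fraction threshold on released endpoint / peak.
#' @return list `dmax`, `diagnostics` (data.frame: candidate, endpoint
#'   fraction, chi2), `satisfied` (logical).
#' @export
select_dmax <- function(profile, alpha = NULL, dmax_range, step = 2,
                        endpoint_fraction = 0.01) {
  qmin <- min(profile$q_grid)
  if (max(dmax_range) > pi / qmin)
    warning("dmax scan extends beyond pi/qmin = ", round(pi / qmin, 1),
            " Å; values there are not reliably determined")
  cand <- seq(dmax_range[1], dmax_range[2], by = step)
  frac <- chi <- numeric(length(cand))
  for (i in seq_along(cand)) {
    rel <- ift(profile, cand[i], alpha = alpha, constrain_dmax = FALSE)
    endv <- mean(utils::tail(rel$pr$p, 2L))
    frac[i] <- endv / max(rel$pr$p)
    chi[i] <- rel$fit_chi2
    if (frac[i] < endpoint_fraction)
      return(list(dmax = cand[i],
                  diagnostics = data.frame(dmax = cand[seq_len(i)],
                                           endpoint_fraction = frac[seq_len(i)],
                                           chi2 = chi[seq_len(i)]),
                  satisfied = TRUE))
  }
  warning("no candidate dmax satisfied the released-endpoint criterion; ",
          "returning the largest candidate")
  list(dmax = cand[length(cand)],
       diagnostics = data.frame(dmax = cand, endpoint_fraction = frac,
                                chi2 = chi),
       satisfied = FALSE)
}

#' Data-quality report for an intensity profile
#'
#' Reports the measured q range, the largest reliably characterizable
#' dimension `pi / q_min`, and the number of points in the Guinier window
#' (q Rg <= max_qrg after skipping `n_skip` leading points).
#'
#' @param profile an [intensity_profile()].
#' @param rg_hint Rg used to delimit the Guinier window (e.g. from
#'   [guinier_fit()]); NA skips the count.
#' @param max_qrg Guinier validity limit.
#' @param n_skip leading points excluded.
#' @return list `q_min`, `q_max`, `dmax_limit`, `n_guinier_points`, `notes`.
#' @export
data_quality <- function(profile, rg_hint = NA, max_qrg = 1.3, n_skip = 0) {
  q <- profile$q_grid
  qmin <- min(q); qmax <- max(q)
  n_g <- NA_integer_
  notes <- character(0)
  if (!is.na(rg_hint)) {
    n_g <- sum(q[(n_skip + 1L):length(q)] * rg_hint <= max_qrg)
    if (n_g < 20L)
      notes <- c(notes, sprintf("only %d points in the Guinier region", n_g))
  }
  if (n_skip > 0)
    notes <- c(notes, sprintf("first %d points excluded from Guinier analysis",
                              n_skip))
  list(q_min = qmin, q_max = qmax, dmax_limit = pi / qmin,
       n_guinier_points = n_g, notes = notes)
}

AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
MASS_WATER <- 18.0153

#' Molecular mass from a protein sequence
#'
#' Sum of average amino-acid residue masses plus one water.
#'
#' @param sequence 1-letter amino-acid string.
#' @return mass in Da.
#' @export
mass_from_sequence <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  m <- AA_MASS[aa]
  if (anyNA(m)) {
    bad <- unique(aa[is.na(m)])
    if (!identical(bad, "X"))
      stop("unknown residue letter(s): ", paste(setdiff(bad, "X"), collapse = ", "))
    m[is.na(m)] <- mean(AA_MASS)   # X: average residue
  }
  sum(m) + MASS_WATER
}
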