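# NNLS ensemble selection against experimental P(r) or I(q) targets, with
# composite profiles, optimally scaled chi-square diagnostics, and ensemble
# statistics (rms <Rg>, <dmax>, maximum dmax with its fraction).

profile_values <- function(x) {
  if (inherits(x, "intensity_profile")) x$intensity
  else if (inherits(x, "distance_distribution")) x$p
  else as.numeric(x)
}

profile_grid <- function(x) {
  if (inherits(x, "intensity_profile")) x$q_grid
  else if (inherits(x, "distance_distribution")) x$r_grid
  else seq_along(x)
}

# align a pool member profile onto the target grid (zero-fill beyond a
# member's dmax for P(r); linear interpolation within range)
align_to_grid <- function(profile, grid) {
  g <- profile_grid(profile)
  v <- profile_values(profile)
  if (length(g) == length(grid) && max(abs(g - grid)) < 1e-9) return(v)
  stats::approx(g, v, xout = grid, rule = 2, yleft = 0, yright = 0)$y
}

#' Fit an NNLS-weighted ensemble to a target profile
#'
#' Builds the design matrix from the pool profiles (each aligned to the
#' target grid), solves the non-negative least-squares problem, drops
#' members whose raw coefficient is below `1e-8` of the largest (numerical
#' dust), renormalizes the surviving fractions to sum 1, and assembles the
#' composite profile and fit diagnostics.
#'
#' For an intensity target the chi-square is computed after optimal scaling
#' of the composite ([scale_and_chi2()]); for a P(r) target it is the
#' (sigma-weighted, when `error_weighted`) mean squared residual of the
#' composite against the target.
#'
#' @param pool_profiles list of `distance_distribution`s or
#'   [intensity_profile()]s, one per pool member.
#' @param target the experimental profile of the same kind.
#' @param error_weighted weight rows by 1/sigma of the target (requires a
#'   sigma/errors column). Default FALSE: P(r)-target fits follow the
#'   unweighted convention, which avoids suppressing the long-r tail where
#'   IFT errors are largest.
#' @return an `ensemble_fit`: list with `member_ids`, `fractions`,
#'   `raw_coefficients`, `target_kind`, `error_weighted`, `composite`,
#'   `chi2`, `scale`, `residuals`.
#' @export
fit_ensemble <- function(pool_profiles, target, error_weighted = FALSE) {
  if (length(pool_profiles) == 0L) stop("empty pool")
  kind <- if (inherits(target, "intensity_profile")) "iq" else "pr"
  grid <- profile_grid(target)
  y <- profile_values(target)
  sig <- if (kind == "iq") target$sigma else target$errors
  if (error_weighted && is.null(sig))
    stop("error weighting requested but the target has no sigma")
  A <- vapply(pool_profiles, align_to_grid, numeric(length(grid)), grid = grid)
  wgt <- if (error_weighted) 1 / sig
  sol <- nnls_solve(A, y, weights = wgt)
  keep <- which(sol$x > 1e-8 * max(sol$x))
  if (length(keep) == 0L) stop("NNLS selected no members")
  frac <- sol$x[keep] / sum(sol$x[keep])
  comp_v <- drop(A[, keep, drop = FALSE] %*% sol$x[keep])
  composite <- if (kind == "iq")
    intensity_profile(grid, comp_v, label = "NNLS composite")
  else distance_distribution(grid, comp_v, normalization = "composite")
  if (kind == "iq" && !is.null(sig)) {
    sc <- scale_and_chi2(composite, target)
    chi2 <- sc$chi2; scale <- sc$scale; resid <- sc$residuals
  } else {
    resid <- (comp_v - y) / if (!is.null(sig)) sig else 1
    chi2 <- sum(resid^2) / max(length(y) - 1L, 1L)
    scale <- 1
  }
  structure(list(member_ids = keep, fractions = frac,
                 raw_coefficients = sol$x[keep], target_kind = kind,
                 error_weighted = error_weighted, composite = composite,
                 chi2 = chi2, scale = scale, residuals = resid),
            class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("<ensemble_fit> %d members on %s target%s, chi2 = %.4g\n",
              length(x$member_ids), x$target_kind,
              if (x$error_weighted) " (error-weighted)" else "", x$chi2))
  ord <- order(x$fractions, decreasing = TRUE)
  cat("  member fractions:",
      paste(sprintf("#%d %.1f%%", x$member_ids[ord],
                    100 * x$fractions[ord]), collapse = ", "), "\n")
  invisible(x)
}

#' Fraction-weighted composite of profiles
#'
#' @param profiles list of profiles on a common grid.
#' @param fractions non-negative weights summing to 1.
#' @return profile of the same kind (model curve; no error propagation).
#' @export
composite_profile <- function(profiles, fractions) {
  if (length(profiles) != length(fractions)) stop("profiles/fractions mismatch")
  if (abs(sum(fractions) - 1) > 1e-6) stop("fractions must sum to 1")
  grid <- profile_grid(profiles[[1]])
  A <- vapply(profiles, align_to_grid, numeric(length(grid)), grid = grid)
  v <- drop(A %*% fractions)
  if (inherits(profiles[[1]], "intensity_profile"))
    intensity_profile(grid, v, label = "composite")
  else distance_distribution(grid, v, normalization = "composite")
}

#' Optimal scale and chi-square of a model intensity against experiment
#'
#' The scale `c` minimizing `sum((c I_m - I_e)^2 / sigma^2)` has the closed
#' form `c = sum(I_m I_e / sigma^2) / sum(I_m^2 / sigma^2)`;
#' `chi2 = 1/(N-1) sum((c I_m - I_e)^2 / sigma^2)` (one degree of freedom
#' spent on the scale). Error-weighted residuals are returned for plots.
#'
#' @param model_iq model [intensity_profile()].
#' @param expt_iq experimental [intensity_profile()] with sigma, same grid.
#' @return list `scale`, `chi2`, `residuals`.
#' @export
scale_and_chi2 <- function(model_iq, expt_iq) {
  if (length(model_iq$q_grid) != length(expt_iq$q_grid) ||
      max(abs(model_iq$q_grid - expt_iq$q_grid)) > 1e-9)
    stop("model and experiment must share the q grid")
  if (is.null(expt_iq$sigma)) stop("experiment must carry sigma")
  n <- length(expt_iq$q_grid)
  if (n < 2L) stop("need at least 2 points")
  Im <- model_iq$intensity; Ie <- expt_iq$intensity; s2 <- expt_iq$sigma^2
  sc <- sum(Im * Ie / s2) / sum(Im^2 / s2)
  resid <- (sc * Im - Ie) / expt_iq$sigma
  list(scale = sc, chi2 = sum(resid^2) / (n - 1L), residuals = resid)
}

#' Ensemble statistics from fit fractions
#'
#' `rg_rms = sqrt(sum(f_i Rg_i^2))` (the r.m.s. fraction-weighted average
#' radius of gyration), `dmax_mean = sum(f_i dmax_i)`, and the largest
#' member dmax with its fraction. Member dmax values come from the members'
#' P(r).
#'
#' @param fit an `ensemble_fit`.
#' @param pool_pr_list list of `distance_distribution`s for the whole pool
#'   (indexed by `fit$member_ids`), or NULL if `pool_dmax_list` is given.
#' @param pool_rg_list numeric Rg values for the whole pool.
#' @param pool_dmax_list optional numeric dmax values for the whole pool.
#' @return list `rg_rms`, `dmax_mean`, `dmax_max`, `dmax_max_fraction`,
#'   `rg_histogram` (data.frame rg, fraction).
#' @export
ensemble_stats <- function(fit, pool_pr_list = NULL, pool_rg_list,
                           pool_dmax_list = NULL) {
  ids <- fit$member_ids; f <- fit$fractions
  rg <- pool_rg_list[ids]
  dmax <- if (!is.null(pool_dmax_list)) pool_dmax_list[ids]
  else vapply(pool_pr_list[ids], function(p) p$dmax, numeric(1))
  imax <- which.max(dmax)
  list(rg_rms = sqrt(sum(f * rg^2)),
       dmax_mean = sum(f * dmax),
       dmax_max = dmax[imax],
       dmax_max_fraction = f[imax],
       rg_histogram = data.frame(rg = rg, fraction = f))
}

#' Refit the union of previously selected members against I(q)
#'
#' Forms the union of the members selected by earlier fits (plus any extra
#' models, e.g. the unmodified predicted structure), recomputes their
#' intensity columns on the target grid, and reruns the NNLS fit. Because
#' the union nests each earlier selection, its residual can only improve.
#'
#' @param fit_list list of `ensemble_fit`s whose members to pool.
#' @param pool_iq_list list of [intensity_profile()]s for the whole pool.
#' @param target_iq experimental [intensity_profile()] target.
#' @param extra_profiles optional list of additional intensity profiles
#'   appended after the pool (e.g. the starting structure).
#' @param error_weighted passed to [fit_ensemble()].
#' @return an `ensemble_fit`; `member_ids` index the union column order,
#'   `union_ids` maps them back to pool indices (extras get NA).
#' @export
refit_union <- function(fit_list, pool_iq_list, target_iq,
                        extra_profiles = NULL, error_weighted = FALSE) {
  ids <- sort(unique(unlist(lapply(fit_list, `[[`, "member_ids"))))
  if (length(ids) == 0L && length(extra_profiles) == 0L) stop("empty union")
  cols <- c(pool_iq_list[ids], extra_profiles)
  fit <- fit_ensemble(cols, target_iq, error_weighted = error_weighted)
  fit$union_ids <- c(ids, rep(NA_integer_, length(extra_profiles)))[fit$member_ids]
  fit
}
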