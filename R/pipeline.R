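# Full workflow orchestration: structure -> segments -> pool -> profiles ->
# fits -> report. Driven by a config list (or YAML file); a thin CLI over
# this function ships in inst/scripts/fit-ensemble.

#' Assemble a run configuration
#'
#' @param structure_path predicted-structure file (PDB/mmCIF, pLDDT in B).
#' @param data_path experimental I(q) .dat file (q, I, sigma).
#' @param pr_path optional GNOM-style .out file with the experimental P(r);
#'   when absent the P(r) target is recomputed by [ift()] from the data.
#' @param segments explicit flexible ranges (2-column matrix / vector), or
#'   NULL to use [suggest_flexible_segments()] at `confidence_threshold`.
#' @param confidence_threshold pLDDT cutoff for automatic segments.
#' @param n_trials Monte Carlo trials.
#' @param stride sub-selection stride.
#' @param seed integer seed for the pool generation.
#' @param dmax fixed dmax in Å or "auto" for [select_dmax()].
#' @param fit_pr,fit_iq which targets to fit.
#' @param max_step_deg Monte Carlo step amplitude, degrees.
#' @param n_skip_low_q leading points excluded from Guinier analysis.
#' @param max_qrg Guinier window limit.
#' @param output_dir directory for reports and artifacts (NULL = no files).
#' @return a `run_config` list.
#' @export
run_config <- function(structure_path = NULL, data_path = NULL,
                       pr_path = NULL, segments = NULL,
                       confidence_threshold = 60, n_trials = 2000,
                       stride = 10, seed = 1L, dmax = "auto",
                       fit_pr = TRUE, fit_iq = TRUE, max_step_deg = 30,
                       n_skip_low_q = 0, max_qrg = 1.3, output_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a YAML run configuration
#'
#' Keys mirror the arguments of [run_config()].
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(run_config, y[names(y) %in% names(formals(run_config))])
  cfg
}

#' Run the full ensemble-modelling pipeline
#'
#' Stages, in order: read and factor-assign the structure; Guinier and
#' quality analysis of the data; P(r) target (from file or by [ift()] with
#' the standardized dmax rule); baseline assessment of the unmodified
#' structure (scaled chi-square against I(q), P(r) overlay); Monte Carlo
#' pool generation over the flexible segments; stride sub-selection with an
#' Rg-distribution representativeness check; per-conformer P(r) and Debye
#' I(q); NNLS fits against the P(r) target (without and with error
#' weighting) and the I(q) target; union refit of all selected members plus
#' the starting structure against I(q). Every random stage records its
#' seed.
#'
#' Either pass a prepared `model` + experimental profiles, or a config
#' pointing at files.
#'
#' @param config a `run_config` (or YAML path).
#' @param model optional pre-built [protein_model()] (overrides
#'   `structure_path`).
#' @param iq optional experimental [intensity_profile()] (overrides
#'   `data_path`).
#' @param pr_target optional experimental `distance_distribution`.
#' @return a `run_report` list; see Details.
#' @details The report carries: `baseline` (chi2 and Rg of the input
#'   structure), `pool` summary, `rg_representativeness`, the fits
#'   (`fit_pr`, `fit_pr_weighted`, `fit_iq`, `fit_union`) each with
#'   chi-square, fractions and ensemble statistics, and `seeds`.
#' @export
run_pipeline <- function(config, model = NULL, iq = NULL, pr_target = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  log_info <- function(...) message(sprintf(...))

  if (is.null(model)) {
    if (is.null(cfg$structure_path)) stop("no structure given")
    model <- read_model(cfg$structure_path)
  }
  if (is.null(model$atoms$b)) model <- assign_scattering_factors(model)
  if (is.null(iq)) {
    if (is.null(cfg$data_path)) stop("no I(q) data given")
    iq <- read_iq(cfg$data_path)
  }

  guinier <- tryCatch(guinier_fit(iq, max_qrg = cfg$max_qrg,
                                  n_skip_low_q = cfg$n_skip_low_q),
                      error = function(e) NULL)
  quality <- data_quality(iq, rg_hint = if (!is.null(guinier)) guinier$rg else NA,
                          max_qrg = cfg$max_qrg, n_skip = cfg$n_skip_low_q)

  if (is.null(pr_target)) {
    if (!is.null(cfg$pr_path)) {
      g <- read_gnom_out(cfg$pr_path)
      pr_target <- rebin_pr(g$pr, 1)
    } else if (!is.null(iq$sigma)) {
      dmax_use <- cfg$dmax
      if (identical(dmax_use, "auto")) {
        hint <- if (!is.null(guinier)) 2.5 * guinier$rg else pi / quality$q_min / 2
        sel <- select_dmax(iq, dmax_range = c(max(20, 0.6 * hint), 1.6 * hint))
        dmax_use <- sel$dmax
        log_info("selected dmax = %.0f Å", dmax_use)
      }
      pr_target <- ift(iq, dmax_use)$pr
    }
  }

  # --- baseline: the unmodified structure ---------------------------------
  pr0 <- compute_pr(model)
  iq0 <- debye_iq(model, iq$q_grid)
  base_chi2 <- if (!is.null(iq$sigma)) scale_and_chi2(iq0, iq)$chi2 else NA
  baseline <- list(chi2 = base_chi2, rg = rg_from_model(model),
                   dmax = pr0$dmax)
  log_info("baseline: Rg %.1f Å, dmax %.0f Å, chi2 %s", baseline$rg,
           baseline$dmax, format(base_chi2, digits = 4))

  # --- segments ------------------------------------------------------------
  segments <- cfg$segments
  if (!is.null(segments) && !inherits(segments, "segment_spec"))
    segments <- segment_spec(segments)
  if (is.null(segments))
    segments <- suggest_flexible_segments(model, cfg$confidence_threshold)
  if (nrow(segments$ranges) == 0L) {
    log_info("no flexible segments: baseline assessment only")
    return(structure(list(config = cfg, baseline = baseline,
                          guinier = guinier, quality = quality,
                          segments = segments, pool = NULL, fits = list(),
                          seeds = list(pool = cfg$seed)),
                     class = "run_report"))
  }

  # --- pool ---------------------------------------------------------------
  pool <- sample_pool(model, segments, n_trials = cfg$n_trials,
                      max_step_deg = cfg$max_step_deg, seed = cfg$seed)
  log_info("pool: accepted %d / %d trials", pool$n_accepted, pool$n_trials)
  sub <- subselect_pool(pool, cfg$stride)
  rep_check <- if (length(sub$models) > 1L)
    compare_rg_distributions(pool, sub) else NULL
  log_info("sub-selected %d of %d (stride %d)", length(sub$models),
           pool$n_accepted, cfg$stride)

  # --- per-conformer profiles ---------------------------------------------
  prs <- lapply(sub$models, compute_pr)
  iqs <- lapply(sub$models, debye_iq, q_grid = iq$q_grid)
  rg_pool <- sub$rg_values
  dmax_pool <- vapply(prs, function(p) p$dmax, numeric(1))

  fits <- list()
  if (isTRUE(cfg$fit_pr) && !is.null(pr_target)) {
    for (ew in c(FALSE, TRUE)) {
      if (ew && is.null(pr_target$errors)) next
      f <- fit_ensemble(prs, pr_target, error_weighted = ew)
      f$stats <- ensemble_stats(f, pool_rg_list = rg_pool,
                                pool_dmax_list = dmax_pool)
      # reciprocal-space diagnostic of the real-space fit
      comp_iq <- composite_profile(iqs[f$member_ids], f$fractions)
      f$chi2_iq <- if (!is.null(iq$sigma)) scale_and_chi2(comp_iq, iq)$chi2 else NA
      fits[[if (ew) "fit_pr_weighted" else "fit_pr"]] <- f
      log_info("P(r) fit%s: %d members, chi2[I(q)] %s, <Rg> %.1f Å",
               if (ew) " (weighted)" else "", length(f$member_ids),
               format(f$chi2_iq, digits = 4), f$stats$rg_rms)
    }
  }
  if (isTRUE(cfg$fit_iq) && !is.null(iq$sigma)) {
    f <- fit_ensemble(iqs, iq, error_weighted = TRUE)
    f$stats <- ensemble_stats(f, pool_rg_list = rg_pool,
                              pool_dmax_list = dmax_pool)
    fits$fit_iq <- f
    log_info("I(q) fit: %d members, chi2 %.4g, <Rg> %.1f Å",
             length(f$member_ids), f$chi2, f$stats$rg_rms)
  }
  if (length(fits) && !is.null(iq$sigma)) {
    f <- refit_union(fits, iqs, iq, extra_profiles = list(iq0),
                     error_weighted = TRUE)
    ids <- f$union_ids
    rg_u <- ifelse(is.na(ids), baseline$rg, rg_pool[ifelse(is.na(ids), 1L, ids)])
    dm_u <- ifelse(is.na(ids), baseline$dmax,
                   dmax_pool[ifelse(is.na(ids), 1L, ids)])
    imax <- which.max(dm_u)
    f$stats <- list(rg_rms = sqrt(sum(f$fractions * rg_u^2)),
                    dmax_mean = sum(f$fractions * dm_u),
                    dmax_max = dm_u[imax], dmax_max_fraction = f$fractions[imax],
                    rg_histogram = data.frame(rg = rg_u, fraction = f$fractions))
    fits$fit_union <- f
    log_info("union refit: %d members, chi2 %.4g", length(f$member_ids), f$chi2)
  }

  report <- structure(
    list(config = cfg, baseline = baseline, guinier = guinier,
         quality = quality, segments = segments,
         pool = list(n_trials = pool$n_trials, n_accepted = pool$n_accepted,
                     n_selected = length(sub$models), stride = cfg$stride,
                     rg_range = range(rg_pool)),
         rg_representativeness = if (!is.null(rep_check))
           rep_check$max_bin_difference else NA,
         pr_target = pr_target, fits = fits,
         seeds = list(pool = cfg$seed)),
    class = "run_report")
  if (!is.null(cfg$output_dir)) write_report(report, sub, cfg$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  baseline: chi2 %s, Rg %.1f Å, dmax %.0f Å\n",
              format(x$baseline$chi2, digits = 4), x$baseline$rg,
              x$baseline$dmax))
  if (!is.null(x$pool))
    cat(sprintf("  pool: %d accepted / %d trials, %d selected\n",
                x$pool$n_accepted, x$pool$n_trials, x$pool$n_selected))
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %s: chi2 %.4g, %d members", nm, f$chi2,
                length(f$member_ids)))
    if (!is.null(f$stats))
      cat(sprintf(", <Rg> %.1f Å, <dmax> %.0f Å, max dmax %.0f Å (%.0f%%)",
                  f$stats$rg_rms, f$stats$dmax_mean, f$stats$dmax_max,
                  100 * f$stats$dmax_max_fraction))
    cat("\n")
  }
  invisible(x)
}

# JSON + CSV + PDB artifacts for a completed run
write_report <- function(report, sub_pool, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(baseline = report$baseline,
             pool = report$pool,
             rg_representativeness = report$rg_representativeness,
             seeds = report$seeds,
             fits = lapply(report$fits, function(f)
               list(member_ids = f$member_ids, fractions = f$fractions,
                    chi2 = f$chi2, scale = f$scale, stats = f$stats[
                      c("rg_rms", "dmax_mean", "dmax_max", "dmax_max_fraction")])))
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (nm in names(report$fits)) {
    f <- report$fits[[nm]]
    utils::write.csv(data.frame(member = f$member_ids, fraction = f$fractions),
                     file.path(dir, paste0(nm, "_fractions.csv")),
                     row.names = FALSE)
  }
  if (!is.null(report$fits$fit_union) && length(sub_pool$models)) {
    ids <- report$fits$fit_union$union_ids
    ids <- ids[!is.na(ids)]
    if (length(ids))
      write_pool(sub_pool$models[ids], file.path(dir, "selected_members.pdb"))
  }
  invisible(dir)
}
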