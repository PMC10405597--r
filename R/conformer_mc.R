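# Torsion-angle Monte Carlo over flexible segments.
#
# Move set: one trial = one pivot rotation of a single backbone dihedral
# (phi or psi; for single-bead chains, the pseudo-dihedral about the virtual
# bond to the next bead) of a residue drawn uniformly from the flexible
# segments, by a uniform angle in +/- max_step_deg. All atoms C-terminal of
# the rotated bond move rigidly; everything N-terminal of it is fixed, so
# bond lengths, bond angles and all intra-rigid-segment geometry are exactly
# preserved. A trial is accepted iff the resulting structure is clash-free.

#' Steric-clash test
#'
#' Counts heavy-atom pairs closer than
#' `overlap_fraction * (radius_i + radius_j)`, excluding directly bonded
#' (1-2) and angle (1-3) neighbours. United-atom group radii are inflated
#' relative to van der Waals radii, hence the default overlap fraction of
#' 0.8.
#'
#' @param model a [protein_model()] with scattering factors (radii) assigned.
#' @param clash_params list with `overlap_fraction` (default 0.8).
#' @param exclusions optional precomputed exclusion structure from
#'   [clash_exclusions()] (recomputed when NULL).
#' @return list `is_clash_free` (logical), `n_clashes` (integer).
#' @export
clash_check <- function(model, clash_params = list(overlap_fraction = 0.8),
                        exclusions = NULL) {
  if (is.null(model$atoms$radius)) stop("assign scattering factors (radii) first")
  f <- clash_params$overlap_fraction %||% 0.8
  if (is.null(exclusions)) exclusions <- clash_exclusions(model)
  n <- nrow(model$atoms)
  d <- dist(coords(model))
  lim <- f * outer(model$atoms$radius, model$atoms$radius, "+")
  lim <- lim[lower.tri(lim)]
  clash <- d < lim
  clash[exclusions$excluded_condensed] <- FALSE
  n_cl <- sum(clash)
  list(is_clash_free = n_cl == 0L, n_clashes = n_cl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1-2 and 1-3 pair exclusions as indices into the condensed (lower-triangle,
# column-major as in stats::dist) pair vector.
clash_exclusions <- function(model) {
  bonds <- model$bonds %||% infer_bonds(model)
  n <- nrow(model$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  pairs <- bonds
  for (i in seq_len(n)) {          # 1-3: two atoms sharing a neighbour
    nb <- adj[[i]]
    if (length(nb) > 1L) pairs <- rbind(pairs, t(utils::combn(sort(nb), 2L)))
  }
  lo <- pmin(pairs[, 1], pairs[, 2]); hi <- pmax(pairs[, 1], pairs[, 2])
  keep <- !duplicated(cbind(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]
  # condensed index of pair (lo < hi): n*(lo-1) - lo*(lo-1)/2 + hi - lo
  idx <- n * (lo - 1) - lo * (lo - 1) / 2 + hi - lo
  list(excluded_condensed = as.integer(idx), bonds = bonds)
}

rodrigues <- function(xyz, origin, axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  v <- sweep(xyz, 2, origin)
  ct <- cos(theta); st <- sin(theta)
  kv <- cbind(k[2] * v[, 3] - k[3] * v[, 2],
              k[3] * v[, 1] - k[1] * v[, 3],
              k[1] * v[, 2] - k[2] * v[, 1])
  kd <- drop(v %*% k)
  out <- v * ct + kv * st + outer(kd * (1 - ct), k)
  sweep(out, 2, origin, "+")
}

# Moving atom set and rotation axis for a dihedral move.
# all-atom:  phi(k): axis N(k)->CA(k), moves CB/C/O of k and all later residues
#            psi(k): axis CA(k)->C(k), moves C=O of k and all later residues
# bead:      axis CA(k)->CA(k+1), moves residues > k
dihedral_move <- function(model, res, angle_type) {
  at <- model$atoms
  bead <- all(tabulate(factor(at$resno)) <= 1L)
  if (bead) {
    i1 <- which(at$resno == res)
    i2 <- which(at$resno == res + 1L)
    if (!length(i1) || !length(i2)) return(NULL)
    moving <- which(at$resno > res)
  } else if (angle_type == "phi") {
    i1 <- which(at$resno == res & at$elety == "N")
    i2 <- which(at$resno == res & at$elety == "CA")
    if (!length(i1) || !length(i2)) return(NULL)
    moving <- which(at$resno > res |
                      (at$resno == res & !(at$elety %in% c("N", "CA"))))
  } else {
    i1 <- which(at$resno == res & at$elety == "CA")
    i2 <- which(at$resno == res & at$elety == "C")
    if (!length(i1) || !length(i2)) return(NULL)
    moving <- which(at$resno > res |
                      (at$resno == res & at$elety == "O"))
  }
  if (!length(moving)) return(NULL)
  list(origin = unlist(at[i1[1], c("x", "y", "z")], use.names = FALSE),
       tip = unlist(at[i2[1], c("x", "y", "z")], use.names = FALSE),
       moving = moving)
}

#' Generate a clash-free conformer pool by dihedral Monte Carlo
#'
#' Each trial perturbs one backbone dihedral of one residue drawn uniformly
#' from the flexible segments by a uniform angle in `±max_step_deg` degrees
#' and keeps the structure iff it passes [clash_check()]. Accepted
#' conformers accumulate from the current structure (a random walk in
#' torsion space), so the pool explores conformations increasingly far from
#' the start. The run is reproducible from `seed`.
#'
#' @param model starting [protein_model()] with factors assigned.
#' @param segments a [segment_spec()] of flexible residue ranges.
#' @param n_trials number of Monte Carlo trials (>= 1).
#' @param max_step_deg maximum dihedral step, degrees in (0, 180].
#' @param seed integer RNG seed.
#' @param clash_params passed to [clash_check()].
#' @return a `conformer_pool`: list with `models`, `rg_values`, `n_trials`,
#'   `n_accepted`, `stride` (1), `seed`, `segments`.
#' @export
sample_pool <- function(model, segments, n_trials = 2000, max_step_deg = 30,
                        seed = 1L, clash_params = list(overlap_fraction = 0.8)) {
  res_ok <- segment_residues(segments)
  if (length(res_ok) == 0L) stop("segments empty: nothing to sample")
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (max_step_deg <= 0 || max_step_deg > 180)
    stop("max_step_deg must be in (0, 180]")
  if (is.null(model$bonds)) model$bonds <- infer_bonds(model)
  excl <- clash_exclusions(model)
  # residues whose psi/virtual-bond move needs a following residue
  nres <- max(model$atoms$resno)
  bead <- all(tabulate(factor(model$atoms$resno)) <= 1L)
  if (bead) res_ok <- res_ok[res_ok < nres]
  if (!length(res_ok)) stop("segments contain no movable residues")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  cur <- model
  models <- vector("list", n_trials)
  rg <- numeric(n_trials)
  n_acc <- 0L
  for (t in seq_len(n_trials)) {
    res <- res_ok[sample.int(length(res_ok), 1L)]
    ang <- if (bead) "virtual" else c("phi", "psi")[sample.int(2L, 1L)]
    mv <- dihedral_move(cur, res, ang)
    if (is.null(mv)) next
    theta <- stats::runif(1, -max_step_deg, max_step_deg) * pi / 180
    trial <- cur
    xyz <- coords(trial)
    xyz[mv$moving, ] <- rodrigues(xyz[mv$moving, , drop = FALSE],
                                  mv$origin, mv$tip - mv$origin, theta)
    coords(trial) <- xyz
    ck <- clash_check(trial, clash_params, exclusions = excl)
    if (ck$is_clash_free) {
      cur <- trial
      n_acc <- n_acc + 1L
      models[[n_acc]] <- cur
      rg[n_acc] <- rg_from_model(cur)
    }
  }
  if (n_acc == 0L)
    warning("zero acceptances after ", n_trials, " trials; empty pool")
  structure(list(models = models[seq_len(n_acc)],
                 rg_values = rg[seq_len(n_acc)],
                 n_trials = n_trials, n_accepted = n_acc,
                 stride = 1L, seed = seed, segments = segments),
            class = "conformer_pool")
}

#' @export
print.conformer_pool <- function(x, ...) {
  cat(sprintf(paste0("<conformer_pool> %d models (accepted %d / %d trials,",
                     " stride %d, seed %d)\n"),
              length(x$models), x$n_accepted, x$n_trials, x$stride, x$seed))
  if (length(x$rg_values))
    cat(sprintf("  Rg range %.1f - %.1f Å\n", min(x$rg_values), max(x$rg_values)))
  invisible(x)
}

#' Sub-select a representative pool
#'
#' Keeps the last conformer of each complete block of `stride`, i.e.
#' `floor(n / stride)` models with order preserved (one in every `stride`).
#'
#' @param pool a `conformer_pool`.
#' @param stride positive integer.
#' @return the thinned `conformer_pool` (records the stride used).
#' @export
subselect_pool <- function(pool, stride) {
  if (stride < 1L) stop("stride must be >= 1")
  n <- length(pool$models)
  keep <- if (stride > n) {
    warning("stride exceeds pool size; empty pool")
    integer(0)
  } else seq.int(stride, n, by = stride)
  pool$models <- pool$models[keep]
  pool$rg_values <- pool$rg_values[keep]
  pool$stride <- as.integer(stride)
  pool
}

#' Compare Rg distributions of two pools
#'
#' Density-normalized histograms on a shared bin grid, plus the maximum
#' absolute per-bin density difference -- the "representativeness" check for
#' a sub-selected pool against its original pool.
#'
#' @param poolA,poolB `conformer_pool`s (or plain numeric Rg vectors).
#' @param n_bins number of shared bins (default 20).
#' @return list `histogramA`, `histogramB` (hist objects),
#'   `max_bin_difference`.
#' @export
compare_rg_distributions <- function(poolA, poolB, n_bins = 20) {
  rgA <- if (is.numeric(poolA)) poolA else poolA$rg_values
  rgB <- if (is.numeric(poolB)) poolB else poolB$rg_values
  if (!length(rgA) || !length(rgB)) stop("empty pool")
  rng <- range(c(rgA, rgB))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  hA <- graphics::hist(rgA, breaks = breaks, plot = FALSE)
  hB <- graphics::hist(rgB, breaks = breaks, plot = FALSE)
  list(histogramA = hA, histogramB = hB,
       max_bin_difference = max(abs(hA$density - hB$density)))
}
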