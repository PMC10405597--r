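# Synthetic flexible proteins with known ground truth.
#
# Pseudo-atomic chains: one bead per residue at the C-alpha position with a
# fixed virtual bond of 3.8 Å, compact self-avoiding domains and extended
# linkers. Beads use the "BEA" residue type of the scattering table (54
# electrons -- an average residue -- radius 3 Å), so every downstream stage
# (factors, P(r), Debye, MC, NNLS) runs on identical code paths to the
# all-atom case.

BOND_BEAD <- 3.8     # virtual C-alpha - C-alpha bond, Å
MIN_SEP_BEAD <- 5.0  # self-avoidance for non-neighbour beads, Å

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

rand_unit <- function() {
  repeat {
    v <- stats::runif(3, -1, 1)
    n2 <- sum(v^2)
    if (n2 > 1e-6 && n2 <= 1) return(v / sqrt(n2))
  }
}

# Grow n beads continuing the chain in `existing` (last row = current chain
# end, the bonded predecessor). Each candidate keeps the fixed virtual bond
# to its predecessor and MIN_SEP_BEAD to every other placed bead; `accept`
# optionally imposes a region constraint; `propose` draws the step
# direction. Returns the n new rows or NULL on failure.
grow_chain <- function(existing, n, propose, accept = NULL,
                       max_retry = 100L, max_backtrack = 400L) {
  pts <- matrix(NA_real_, n, 3)
  i <- 1L
  n_back <- 0L
  while (i <= n) {
    cur <- if (i == 1L) existing[nrow(existing), ] else pts[i - 1L, ]
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      cand <- cur + BOND_BEAD * propose()
      if (!is.null(accept) && !accept(cand)) next
      prev <- rbind(existing, pts[seq_len(i - 1L), , drop = FALSE])
      prev <- prev[-nrow(prev), , drop = FALSE]   # bonded predecessor exempt
      if (nrow(prev) > 0L &&
          min(rowSums(sweep(prev, 2, cand)^2)) < MIN_SEP_BEAD^2) next
      pts[i, ] <- cand
      placed <- TRUE
      break
    }
    if (placed) { i <- i + 1L; next }
    # walk trapped: unwind a few beads and try again
    n_back <- n_back + 1L
    if (n_back > max_backtrack) return(NULL)
    i <- max(1L, i - 3L)
  }
  pts
}

grow_domain <- function(existing, n, center, R) {
  grow_chain(existing, n, propose = rand_unit,
             accept = function(p) sum((p - center)^2) <= R^2)
}

# extended linker: steps biased along `direction` with angular jitter
grow_linker <- function(existing, n, direction) {
  dirn <- direction / sqrt(sum(direction^2))
  grow_chain(existing, n, propose = function() {
    step <- dirn + 0.35 * stats::rnorm(3)
    step / sqrt(sum(step^2))
  })
}

#' Generate a pseudo-atomic multi-domain flexible protein
#'
#' Builds a single-bead-per-residue chain of `n_domains` compact
#' self-avoiding domains joined by extended linkers of `linker_length`
#' residues, with valid virtual-bond connectivity for the Monte Carlo
#' sampler. Confidence is set to 90 (pLDDT) inside domains and 30 in
#' linkers, mimicking the folded-domain / unstructured-linker signature of
#' predicted structures. Scattering beads carry a constant per-residue
#' electron count.
#'
#' @param n_domains number of folded domains (>= 1).
#' @param domain_radius confining radius per domain, Å (default 10).
#' @param linker_length residues per linker (default 10).
#' @param seed integer RNG seed; same seed, same coordinates.
#' @param residues_per_domain beads per domain; default scales with the
#'   domain volume (~115 Å^3 per residue).
#' @return a [protein_model()] with scattering factors assigned and bead
#'   bonds recorded.
#' @export
make_flexible_model <- function(n_domains = 2, domain_radius = 10,
                                linker_length = 10, seed = 1L,
                                residues_per_domain = NULL) {
  if (n_domains < 1 || domain_radius <= 0 || linker_length < 0)
    stop("parameters must be positive")
  if (is.null(residues_per_domain))
    residues_per_domain <- max(8L, round(4 / 3 * pi * domain_radius^3 / 115))
  with_seed(seed, {
    for (attempt in 1:25) {
      center <- c(0, 0, 0)
      xyz <- matrix(center, 1, 3)          # first bead seeds the chain
      conf <- 90
      ok <- TRUE
      for (d in seq_len(n_domains)) {
        n_grow <- residues_per_domain - if (d == 1L) 1L else 0L
        dom <- grow_domain(xyz, n_grow, center, domain_radius)
        if (is.null(dom)) { ok <- FALSE; break }
        xyz <- rbind(xyz, dom)
        conf <- c(conf, rep(90, n_grow))
        if (d < n_domains && linker_length > 0) {
          dirn <- rand_unit()
          lk <- grow_linker(xyz, linker_length, dirn)
          if (is.null(lk)) { ok <- FALSE; break }
          xyz <- rbind(xyz, lk)
          conf <- c(conf, rep(30, linker_length))
          center <- lk[nrow(lk), ] + domain_radius * dirn
        }
      }
      if (ok) break
    }
    if (!ok) stop("infeasible geometry after bounded retries")
    n <- nrow(xyz)
    atoms <- data.frame(serial = seq_len(n), elety = "CA", resid = "BEA",
                        chain = "A", resno = seq_len(n),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        confidence = conf, stringsAsFactors = FALSE)
    m <- protein_model(atoms, label = sprintf("synthetic_%dx%d", n_domains, n))
    m$bonds <- cbind(seq_len(n - 1L), 2:n)
    assign_scattering_factors(m)
  })
}

#' Simulate a SAXS experiment from an ensemble with known truth
#'
#' Composes the ensemble-averaged intensity from the Debye curves of the
#' selected pool members weighted by `true_fractions`, adds q-dependent
#' Gaussian noise with `sigma(q) = noise_rel * I(q) + noise_floor`, and
#' returns the noise-free composite P(r) as the real-space truth.
#'
#' @param pool a `conformer_pool` (or plain list of models).
#' @param true_members indices into the pool.
#' @param true_fractions weights aligned with `true_members`, summing to 1.
#' @param q_grid q values, Å^-1.
#' @param noise_rel relative noise level (default 0.02).
#' @param noise_floor additive sigma floor (default 0).
#' @param seed integer RNG seed for the noise draw.
#' @return list `iq` (noisy [intensity_profile()] with the generating sigma
#'   in its sigma column), `pr_truth` (noise-free composite
#'   `distance_distribution`), `truth` (a `synthetic_truth` record).
#' @export
simulate_experiment <- function(pool, true_members, true_fractions, q_grid,
                                noise_rel = 0.02, noise_floor = 0, seed = 1L) {
  models <- if (inherits(pool, "conformer_pool")) pool$models else pool
  if (length(true_members) != length(true_fractions))
    stop("members/fractions mismatch")
  if (abs(sum(true_fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  iqs <- lapply(models[true_members], debye_iq, q_grid = q_grid)
  I <- drop(vapply(iqs, function(p) p$intensity,
                   numeric(length(q_grid))) %*% true_fractions)
  prs <- lapply(models[true_members], compute_pr)
  grid <- seq(0.5, max(vapply(prs, function(p) max(p$r_grid), numeric(1))), 1)
  P <- vapply(prs, align_to_grid, numeric(length(grid)), grid = grid)
  p_true <- drop(P %*% true_fractions)
  self <- sum(vapply(prs, function(p) p$self_term, numeric(1)) * true_fractions)
  sig <- noise_rel * I + noise_floor
  I_obs <- if (all(sig == 0)) I else
    with_seed(seed, I + stats::rnorm(length(I), 0, sig))
  iq <- intensity_profile(q_grid, I_obs,
                          sigma = if (all(sig == 0)) NULL else sig,
                          label = "simulated experiment")
  truth <- structure(list(true_members = true_members,
                          true_fractions = true_fractions,
                          true_rg_values = vapply(models[true_members],
                                                  rg_from_model, numeric(1)),
                          noise_model = c(relative_sd = noise_rel,
                                          floor = noise_floor),
                          seed = seed),
                     class = "synthetic_truth")
  list(iq = iq,
       pr_truth = distance_distribution(grid, p_true, self_term = self),
       truth = truth)
}
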