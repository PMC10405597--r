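# Shared fixtures, built in code and memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# two-domain flexible bead protein used across modules
fix_model <- function() memo("model", make_flexible_model(seed = 3))

fix_segments <- function() memo("segments",
                                suggest_flexible_segments(fix_model()))

fix_pool <- function() memo("pool",
  sample_pool(fix_model(), fix_segments(), n_trials = 400, seed = 11))

# minimal 3-residue all-atom PDB text (backbone + CB), pLDDT in B column
tiny_pdb_lines <- function(conf = c(88.5, 42.1, 63.7)) {
  at <- list(
    c("N", "ALA", 1, 0.0, 0.0, 0.0), c("CA", "ALA", 1, 1.46, 0.0, 0.0),
    c("C", "ALA", 1, 2.0, 1.4, 0.0), c("O", "ALA", 1, 1.3, 2.4, 0.0),
    c("CB", "ALA", 1, 2.0, -0.8, 1.2),
    c("N", "GLY", 2, 3.3, 1.5, 0.0), c("CA", "GLY", 2, 4.0, 2.8, 0.0),
    c("C", "GLY", 2, 5.5, 2.6, 0.2), c("O", "GLY", 2, 6.0, 1.5, 0.4),
    c("N", "SER", 3, 6.2, 3.7, 0.1), c("CA", "SER", 3, 7.65, 3.7, 0.3),
    c("C", "SER", 3, 8.3, 5.05, 0.2), c("O", "SER", 3, 7.7, 6.1, 0.3),
    c("CB", "SER", 3, 8.4, 2.9, 1.4), c("OG", "SER", 3, 8.5, 1.55, 1.05))
  vapply(seq_along(at), function(i) {
    a <- at[[i]]
    sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            i, a[[1]], a[[2]], as.integer(a[[3]]), as.numeric(a[[4]]),
            as.numeric(a[[5]]), as.numeric(a[[6]]), 1.0,
            conf[as.integer(a[[3]])])
  }, character(1))
}

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb"), ...) {
  writeLines(c(tiny_pdb_lines(...), "END"), path)
  path
}

# noise-free sphere form-factor profile (radius R), with nominal errors
sphere_profile <- function(R = 50, I0 = 1000, qmax = 0.3, dq = 0.002,
                           noise_frac = 0.01) {
  q <- seq(2 * dq, qmax, by = dq)
  FF <- (3 * (sin(q * R) - q * R * cos(q * R)) / (q * R)^3)^2
  I <- I0 * FF
  intensity_profile(q, I, sigma = noise_frac * (abs(I) + 1e-4 * I0),
                    label = "sphere")
}

# a lightweight pool of n dummy models (for pure bookkeeping operations)
dummy_pool <- function(n) {
  structure(list(models = as.list(seq_len(n)), rg_values = as.numeric(seq_len(n)),
                 n_trials = n, n_accepted = n, stride = 1L, seed = 0L,
                 segments = segment_spec(c(1, 2))),
            class = "conformer_pool")
}

# random compact atom cloud with unit contrast, for P(r)/Debye oracles
random_model <- function(n = 30, seed = 1, spread = 15) {
  set.seed(seed)
  xyz <- matrix(rnorm(3 * n, sd = spread / 2), n, 3)
  atoms <- data.frame(serial = seq_len(n), elety = "CA", resid = "BEA",
                      chain = "A", resno = seq_len(n),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      confidence = 90)
  m <- protein_model(atoms, label = sprintf("cloud_%d", seed))
  m$bonds <- cbind(seq_len(n - 1L), 2:n)
  assign_scattering_factors(m)
}
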