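test_that("a minimal PDB reads back residues, confidences and sequence", {
  path <- write_tiny_pdb(conf = c(88.5, 42.1, 63.7))
  m <- read_model(path)
  expect_s3_class(m, "protein_model")
  expect_equal(length(unique(m$atoms$resno)), 3L)
  expect_equal(m$sequence, "AGS")
  per_res <- m$atoms$confidence[!duplicated(m$atoms$resno)]
  expect_equal(per_res, c(88.5, 42.1, 63.7))
  # atoms inherit their residue's CA confidence
  expect_equal(unique(m$atoms$confidence[m$atoms$resno == 1]), 88.5)
})

test_that("HETATM-only and empty files are rejected", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A 401      10.000  10.000  10.000  1.00 20.00",
    "END"), path)
  expect_error(read_model(path), "empty model|Error in read")
  expect_error(read_model(tempfile(fileext = ".pdb")), "no such file")
})

test_that("scattering factor assignment follows the water-displacement rule", {
  # b0(r_wat) = 10 exactly; b0 = 0 at zero radius; strictly increasing
  expect_equal(b0_from_radius(1.93), 10)
  expect_equal(b0_from_radius(0), 0)
  r <- seq(0.5, 3, by = 0.1)
  expect_true(all(diff(b0_from_radius(r)) > 0))
  # united CH2 group: b = 8 electrons, b0 from its radius by direct arithmetic
  m <- assign_scattering_factors(read_model(write_tiny_pdb()))
  cb <- m$atoms[m$atoms$elety == "CB" & m$atoms$resid == "ALA", ]
  expect_equal(cb$b, 9)   # CB of alanine is a CH3 group
  ser_cb <- m$atoms[m$atoms$elety == "CB" & m$atoms$resid == "SER", ]
  expect_equal(ser_cb$b, 8)
  expect_equal(ser_cb$b0, 10 * (ser_cb$radius / 1.93)^3)
  expect_true(all(m$atoms$b > 0) && all(m$atoms$b0 >= 0) &&
                all(m$atoms$radius > 0))
})

test_that("unknown atoms are reported by name", {
  path <- write_tiny_pdb()
  m <- read_model(path)
  m$atoms$elety[2] <- "XQ"
  expect_error(assign_scattering_factors(m), "XQ")
})

test_that("segment confidence gives mean and population sd per residue", {
  path <- write_tiny_pdb(conf = c(40, 60, 70))
  m <- read_model(path)
  s <- segment_confidence(m, c(1, 2))
  expect_equal(s$mean, 50)
  expect_equal(s$sd, 10)   # population sd of {40, 60}
  expect_equal(s$n_residues, 2L)
  # whole-model summary equals summary of the full per-residue vector
  s_all <- segment_confidence(m)
  v <- c(40, 60, 70)
  expect_equal(s_all$mean, mean(v))
  expect_equal(s_all$sd, sqrt(mean((v - mean(v))^2)))
  expect_error(segment_confidence(m, c(7, 9)), "empty segment")
})

test_that("flexible-segment suggestion finds maximal low-confidence runs", {
  n <- 100
  conf <- rep(90, n)
  conf[50:80] <- 40
  conf[10:14] <- 40          # run of 5: below min_length 10
  atoms <- data.frame(serial = 1:n, elety = "CA", resid = "BEA", chain = "A",
                      resno = 1:n, x = 3.8 * (1:n), y = 0, z = 0,
                      confidence = conf)
  m <- protein_model(atoms)
  expect_equal(suggest_flexible_segments(m, 60, 10)$ranges,
               matrix(c(50L, 80L), 1, dimnames = list(NULL, c("first", "last"))))
  # brute-force scan oracle over random confidence patterns
  set.seed(42)
  for (rep in 1:5) {
    conf <- sample(c(30, 90), n, replace = TRUE)
    m$atoms$confidence <- conf
    got <- suggest_flexible_segments(m, 60, 3)$ranges
    # oracle: test every residue window directly
    runs <- rle(conf < 60)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    want <- cbind(starts, ends)[runs$values & runs$lengths >= 3, , drop = FALSE]
    expect_equal(unname(got), unname(want))
  }
  m$atoms$confidence <- rep(90, n)
  expect_equal(nrow(suggest_flexible_segments(m, 60)$ranges), 0L)
})

test_that("pool write/read round trip preserves coordinates and Rg", {
  pool <- fix_pool()
  models <- pool$models[1:5]
  path <- tempfile(fileext = ".pdb")
  write_pool(models, path)
  back <- read_pool(path)
  expect_length(back, 5L)
  for (k in 1:5) {
    expect_equal(as.matrix(back[[k]]$atoms[, c("x", "y", "z")]),
                 as.matrix(models[[k]]$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
    m2 <- assign_scattering_factors(back[[k]])
    expect_equal(rg_from_model(m2), pool$rg_values[k], tolerance = 1e-3)
  }
  # write -> read -> write is idempotent at PDB precision
  path2 <- tempfile(fileext = ".pdb")
  write_pool(back, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_error(write_pool(list(), path), "empty")
})
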