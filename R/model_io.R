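# radius of a bulk water molecule (Å); 10 electrons per water
R_WATER <- 1.93
N_ELECTRONS_WATER <- 10

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V", BEA = "X")

#' Construct a protein model
#'
#' A `protein_model` holds an ordered atom table (one row per heavy atom or
#' pseudo-atom bead), the one-letter sequence, and an optional bond list used
#' for clash-check exclusions. Per-residue confidence follows the AlphaFold
#' convention: pLDDT on 0-100, stored in the B-factor column of model files.
#'
#' @param atoms data.frame with columns `serial`, `elety` (atom name),
#'   `resid` (3-letter residue), `chain`, `resno` (1-based residue index),
#'   `x`, `y`, `z` (Å), `confidence` (pLDDT). Scattering columns `b`, `b0`,
#'   `radius` are added by [assign_scattering_factors()].
#' @param label character tag for reports.
#' @param bonds optional 2-column integer matrix of bonded atom-row pairs;
#'   inferred from geometry when `NULL` (see [infer_bonds()]).
#' @return object of class `protein_model`.
#' @export
protein_model <- function(atoms, label = "model", bonds = NULL) {
  need <- c("serial", "elety", "resid", "chain", "resno",
            "x", "y", "z", "confidence")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty model")
  if (is.unsorted(atoms$resno)) stop("residue indices must be non-decreasing in atom order")
  atoms$resno <- as.integer(atoms$resno)
  seq1 <- AA3[atoms$resid[!duplicated(atoms$resno)]]
  seq1[is.na(seq1)] <- "X"
  m <- structure(list(atoms = atoms,
                      sequence = paste(seq1, collapse = ""),
                      label = label,
                      bonds = bonds),
                 class = "protein_model")
  m
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("<protein_model> %s: %d residues, %d atoms", x$label,
              length(unique(x$atoms$resno)), nrow(x$atoms)))
  if (!is.null(x$atoms$b)) cat(" [scattering factors assigned]")
  cat("\n")
  invisible(x)
}

n_residues <- function(model) length(unique(model$atoms$resno))

coords <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

`coords<-` <- function(model, value) {
  model$atoms[, c("x", "y", "z")] <- value
  model
}

#' Read a predicted structure (PDB or mmCIF)
#'
#' Loads heavy atoms of a single protein chain; the B-factor column is taken
#' as per-residue pLDDT confidence (AlphaFold convention: every atom of a
#' residue carries the residue value, which is read from CA). Hydrogens,
#' waters and heteroatoms are dropped; alternate locations beyond the first
#' are discarded.
#'
#' @param path file path.
#' @param format_hint "pdb", "cif", or NULL to guess from the extension.
#' @param chain chain identifier; required if the file has several chains.
#' @return a [protein_model()].
#' @export
read_model <- function(path, format_hint = NULL, chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- format_hint
  if (is.null(fmt)) {
    fmt <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (fmt == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("unparsable structure file: ", conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[is.na(a$alt) | a$alt %in% c("", "A", "1"), , drop = FALSE]
  a <- a[!(a$elesy %in% "H") & !grepl("^[0-9]*H", a$elety), , drop = FALSE]
  if (nrow(a) == 0L) stop("empty model: no protein ATOM records in ", path)
  chains <- unique(a$chain)
  if (length(chains) > 1L) {
    if (is.null(chain))
      stop("multiple chains (", paste(chains, collapse = ","),
           "); pass chain= to select one")
    a <- a[a$chain == chain, , drop = FALSE]
    if (nrow(a) == 0L) stop("no atoms in chain ", chain)
  }
  # per-residue confidence from CA (atoms inherit their residue's value)
  ca <- a[a$elety == "CA", c("resno", "b")]
  conf <- ca$b[match(a$resno, ca$resno)]
  conf[is.na(conf)] <- a$b[is.na(conf)]
  atoms <- data.frame(serial = a$eleno, elety = a$elety, resid = a$resid,
                      chain = a$chain, resno = a$resno,
                      x = a$x, y = a$y, z = a$z, confidence = conf,
                      stringsAsFactors = FALSE)
  protein_model(atoms, label = sub("\\.(pdb|cif)$", "", basename(path),
                                   ignore.case = TRUE))
}

load_factor_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "scattering_groups.tsv",
                        package = "saxsensemble")
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Assign united-atom scattering factors
#'
#' Each heavy atom receives the electron count `b` of its atomic group
#' (implicit hydrogens folded in), a group radius, and the solvent-displaced
#' electron count `b0 = 10 * (radius / 1.93)^3` -- ten electrons per water
#' molecule scaled by the group volume relative to bulk water
#' (radius 1.93 Å). The effective contrast used in all distance-distribution
#' and intensity calculations is `b - b0`.
#'
#' @param model a [protein_model()].
#' @param factor_table data.frame with columns residue/atom/electrons/radius;
#'   defaults to the packaged table.
#' @return the model with `b`, `b0`, `radius`, `b_eff` columns filled in.
#' @export
assign_scattering_factors <- function(model, factor_table = NULL) {
  if (is.null(factor_table) || is.character(factor_table))
    factor_table <- load_factor_table(if (is.character(factor_table)) factor_table)
  key <- paste(model$atoms$resid, model$atoms$elety)
  idx <- match(key, paste(factor_table$residue, factor_table$atom))
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("unknown residue/atom combinations: ",
         paste(utils::head(bad, 10L), collapse = "; "),
         if (length(bad) > 10L) " ..." else "")
  }
  model$atoms$b <- factor_table$electrons[idx]
  model$atoms$radius <- factor_table$radius[idx]
  model$atoms$b0 <- b0_from_radius(model$atoms$radius)
  model$atoms$b_eff <- model$atoms$b - model$atoms$b0
  model
}

#' Solvent-displaced electrons of an atomic group
#'
#' @param radius atomic-group radius in Å.
#' @return `10 * (radius / 1.93)^3` electrons.
#' @export
b0_from_radius <- function(radius) {
  N_ELECTRONS_WATER * (radius / R_WATER)^3
}

#' Summarize per-residue confidence over a segment
#'
#' Mean and population standard deviation of pLDDT over the residues of a
#' segment (one value per residue), the "average prediction confidence
#' level" used to characterize candidate flexible regions.
#'
#' @param model a [protein_model()].
#' @param segment `c(first, last)` residue range (inclusive, 1-based), a
#'   segment_spec, or NULL for the whole model.
#' @return list with `mean`, `sd`, `n_residues`.
#' @export
segment_confidence <- function(model, segment = NULL) {
  per_res <- model$atoms$confidence[!duplicated(model$atoms$resno)]
  resno <- unique(model$atoms$resno)
  if (!is.null(segment)) {
    rng <- if (inherits(segment, "segment_spec")) segment$ranges else
      matrix(segment, ncol = 2)
    keep <- rep(FALSE, length(resno))
    for (i in seq_len(nrow(rng))) keep <- keep | (resno >= rng[i, 1] & resno <= rng[i, 2])
    per_res <- per_res[keep]
  }
  if (length(per_res) == 0L) stop("empty segment")
  n <- length(per_res)
  m <- mean(per_res)
  list(mean = m, sd = sqrt(sum((per_res - m)^2) / n), n_residues = n)
}

#' Flexible-segment specification
#'
#' @param ranges 2-column matrix (or vector of length 2) of inclusive,
#'   1-based first/last residue pairs.
#' @return object of class `segment_spec`.
#' @export
segment_spec <- function(ranges) {
  if (is.list(ranges)) ranges <- do.call(rbind, lapply(ranges, as.numeric))
  if (is.null(dim(ranges))) ranges <- matrix(ranges, ncol = 2, byrow = TRUE)
  ranges <- matrix(as.integer(ranges), ncol = 2,
                   dimnames = list(NULL, c("first", "last")))
  if (any(ranges[, 1] > ranges[, 2])) stop("segment with first > last")
  o <- order(ranges[, 1])
  ranges <- ranges[o, , drop = FALSE]
  if (nrow(ranges) > 1L &&
      any(ranges[-1L, 1] <= ranges[-nrow(ranges), 2]))
    stop("overlapping segments")
  structure(list(ranges = ranges), class = "segment_spec")
}

#' @export
print.segment_spec <- function(x, ...) {
  if (nrow(x$ranges) == 0L) cat("<segment_spec> (empty)\n")
  else cat("<segment_spec>",
           paste(sprintf("%d-%d", x$ranges[, 1], x$ranges[, 2]), collapse = ", "),
           "\n")
  invisible(x)
}

segment_residues <- function(spec) {
  if (nrow(spec$ranges) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(spec$ranges)),
                function(i) spec$ranges[i, 1]:spec$ranges[i, 2]))
}

#' Propose flexible segments from low-confidence runs
#'
#' Maximal runs of at least `min_length` consecutive residues whose pLDDT
#' falls below `confidence_threshold`. Advisory only: an explicit user
#' segment specification always overrides the suggestion.
#'
#' @param model a [protein_model()].
#' @param confidence_threshold pLDDT cutoff (default 60).
#' @param min_length shortest reported run (default 5 residues).
#' @return a [segment_spec()] (possibly empty).
#' @export
suggest_flexible_segments <- function(model, confidence_threshold = 60,
                                      min_length = 5) {
  if (confidence_threshold <= 0 || min_length <= 0)
    stop("thresholds must be positive")
  keep <- !duplicated(model$atoms$resno)
  resno <- model$atoms$resno[keep]
  low <- model$atoms$confidence[keep] < confidence_threshold
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= min_length
  if (!any(sel))
    return(structure(list(ranges = matrix(integer(0), ncol = 2,
                                          dimnames = list(NULL, c("first", "last")))),
                     class = "segment_spec"))
  segment_spec(cbind(resno[starts[sel]], resno[ends[sel]]))
}

# ---- pool (multi-model PDB) I/O -------------------------------------------

fmt_atom_line <- function(a) {
  # PDB fixed-width ATOM record; atom names left-padded per convention
  name <- ifelse(nchar(a$elety) >= 4L, a$elety, sprintf(" %-3s", a$elety))
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          a$serial %% 100000L, name, a$resid, substr(a$chain, 1, 1), a$resno,
          a$x, a$y, a$z, 1.00, a$confidence)
}

#' Write models to a (multi-model) PDB file
#'
#' Models are wrapped in MODEL/ENDMDL records; coordinates at PDB precision
#' (3 decimals) and confidence in the B-factor column.
#'
#' @param models a `protein_model` or list of them (all with identical atom
#'   counts), or a [conformer_pool].
#' @param path output file.
#' @export
write_pool <- function(models, path) {
  if (inherits(models, "conformer_pool")) models <- models$models
  if (inherits(models, "protein_model")) models <- list(models)
  if (length(models) == 0L) stop("empty model list")
  n_at <- vapply(models, function(m) nrow(m$atoms), integer(1))
  if (length(unique(n_at)) != 1L)
    stop("inconsistent atom counts across models")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(models)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(fmt_atom_line(models[[i]]$atoms), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a MODEL/ENDMDL-delimited multi-model PDB
#'
#' @param path file path.
#' @return list of [protein_model()]s in file order.
#' @export
read_pool <- function(path) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ")
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) starts <- 1L
  ends <- c(starts[-1L] - 1L, length(lines))
  models <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    sel <- which(is_atom & seq_along(lines) >= starts[k] &
                   seq_along(lines) <= ends[k])
    if (length(sel) == 0L) stop("model block ", k, " has no ATOM records")
    ln <- lines[sel]
    atoms <- data.frame(
      serial = as.integer(substr(ln, 7, 11)),
      elety = trimws(substr(ln, 13, 16)),
      resid = trimws(substr(ln, 18, 20)),
      chain = substr(ln, 22, 22),
      resno = as.integer(substr(ln, 23, 26)),
      x = as.numeric(substr(ln, 31, 38)),
      y = as.numeric(substr(ln, 39, 46)),
      z = as.numeric(substr(ln, 47, 54)),
      confidence = as.numeric(substr(ln, 61, 66)),
      stringsAsFactors = FALSE)
    models[[k]] <- protein_model(atoms, label = sprintf("model_%d", k))
  }
  n_at <- vapply(models, function(m) nrow(m$atoms), integer(1))
  if (length(unique(n_at)) != 1L)
    stop("inconsistent atom counts across models")
  models
}

#' Infer covalent bonds from geometry
#'
#' Heavy-atom pairs in the same or adjacent residues closer than `cutoff`
#' are taken as bonded; for single-bead-per-residue models (pseudo-atomic
#' chains) consecutive beads are bonded regardless of distance. Used only to
#' build the 1-2/1-3 exclusion list of [clash_check()].
#'
#' @param model a [protein_model()].
#' @param cutoff bond-distance cutoff in Å (default 1.9).
#' @return 2-column matrix of atom-row indices.
#' @export
infer_bonds <- function(model, cutoff = 1.9) {
  at <- model$atoms
  n <- nrow(at)
  if (all(tabulate(factor(at$resno)) <= 1L)) {
    # bead chain: consecutive residues are bonded
    ii <- seq_len(n - 1L)
    return(cbind(ii, ii + 1L))
  }
  xyz <- coords(model)
  out <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    j <- which(at$resno > at$resno[i] - 2L & at$resno < at$resno[i] + 2L)
    j <- j[j > i]
    if (!length(j)) next
    d2 <- (xyz[j, 1] - xyz[i, 1])^2 + (xyz[j, 2] - xyz[i, 2])^2 +
      (xyz[j, 3] - xyz[i, 3])^2
    hit <- j[d2 < cutoff^2]
    if (length(hit)) out[[i]] <- cbind(i, hit)
  }
  do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                   list(matrix(integer(0), ncol = 2))))
}
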