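# Conformer ensembles: data model, loading, and geometric/energetic curation.

HARTREE_TO_KJMOL <- 2625.499
GAS_CONSTANT <- 8.3145  # J / (K mol)

#' Create a conformer
#'
#' A conformer is one molecular geometry together with its relative energy and
#' (optionally) per-nucleus computed NMR quantities.
#'
#' @param id Character id, unique within an ensemble.
#' @param elements Character vector of element symbols, one per atom.
#' @param coords Numeric N x 3 matrix of Cartesian coordinates in Angstrom.
#' @param rel_energy Relative energy in kJ/mol (finite; re-referenced to the
#'   ensemble minimum by [ensemble()]).
#' @param shieldings Optional named numeric vector of isotropic shieldings
#'   (ppm), names are 1-based atom indices.
#' @param couplings Optional data frame with columns `pair_id`, `J_hz` of
#'   computed 3JHH couplings.
#' @param ff_tag Character tag naming the source force field.
#' @return An object of class `conformer`.
#' @export
conformer <- function(id, elements, coords, rel_energy,
                      shieldings = NULL, couplings = NULL, ff_tag = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("coords must have 3 columns, got ", ncol(coords))
  if (length(elements) != nrow(coords))
    stop("conformer '", id, "': ", length(elements), " elements but ",
         nrow(coords), " coordinate rows")
  if (!is.finite(rel_energy))
    stop("conformer '", id, "': rel_energy must be finite")
  if (!is.null(shieldings)) {
    idx <- as.integer(names(shieldings))
    if (anyNA(idx) || any(idx < 1L) || any(idx > nrow(coords)))
      stop("conformer '", id, "': shielding index outside 1..", nrow(coords))
  }
  structure(list(id = as.character(id), elements = as.character(elements),
                 coords = coords, rel_energy = as.numeric(rel_energy),
                 shieldings = shieldings, couplings = couplings,
                 ff_tag = ff_tag),
            class = "conformer")
}

#' Create a conformer ensemble
#'
#' An ensemble is the ordered conformer collection for one
#' (molecule, candidate stereoisomer, force field) triple. All conformers must
#' share the same atom ordering; relative energies are re-referenced so the
#' minimum is exactly zero.
#'
#' @param conformers List of [conformer()] objects.
#' @param molecule_id,candidate_id,ff_tag Identifying strings.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(conformers, molecule_id = "", candidate_id = "",
                     ff_tag = "") {
  if (length(conformers) == 0L) stop("ensemble must contain >= 1 conformer")
  ids <- vapply(conformers, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate conformer ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ref <- conformers[[1L]]$elements
  for (cf in conformers) {
    if (length(cf$elements) != length(ref) || !all(cf$elements == ref))
      stop("conformer '", cf$id,
           "' does not share the ensemble atom list/ordering")
  }
  e <- vapply(conformers, `[[`, numeric(1), "rel_energy")
  shift <- min(e)
  conformers <- lapply(conformers, function(cf) {
    cf$rel_energy <- cf$rel_energy - shift
    cf
  })
  structure(list(molecule_id = molecule_id, candidate_id = candidate_id,
                 ff_tag = ff_tag, conformers = conformers),
            class = "ensemble")
}

#' @export
length.ensemble <- function(x) length(x$conformers)

#' @export
print.ensemble <- function(x, ...) {
  e <- rel_energies(x)
  cat(sprintf("<ensemble> molecule='%s' candidate='%s' ff='%s': %d conformers, energies 0..%.2f kJ/mol\n",
              x$molecule_id, x$candidate_id, x$ff_tag, length(x),
              max(e)))
  invisible(x)
}

#' Relative energies of an ensemble
#' @param e An [ensemble()].
#' @return Named numeric vector of relative energies (kJ/mol).
#' @export
rel_energies <- function(e) {
  stats::setNames(vapply(e$conformers, `[[`, numeric(1), "rel_energy"),
                  conformer_ids(e))
}

#' Conformer ids of an ensemble
#' @param e An [ensemble()].
#' @export
conformer_ids <- function(e) {
  vapply(e$conformers, `[[`, character(1), "id")
}

subset_ensemble <- function(e, keep) {
  ensemble(e$conformers[keep], e$molecule_id, e$candidate_id, e$ff_tag)
}

## ---- loading -------------------------------------------------------------

energy_to_kjmol <- function(value, unit) {
  switch(tolower(unit),
         "kj/mol" = , "kjmol" = , "kj" = value,
         "hartree" = , "au" = value * HARTREE_TO_KJMOL,
         stop("unknown energy unit '", unit,
              "' (declare 'kJ/mol' or 'hartree'; units are never guessed)"))
}

parse_xyz_blocks <- function(lines, path) {
  blocks <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop("malformed geometry block in '", path, "' at line ", i,
           ": expected an atom count, got '", lines[i], "'")
    if (i + 1L + nat > length(lines))
      stop("truncated geometry block in '", path, "' starting at line ", i)
    comment <- lines[i + 1L]
    at <- lines[(i + 2L):(i + 1L + nat)]
    tok <- strsplit(trimws(at), "\\s+")
    bad <- which(vapply(tok, length, integer(1)) < 4L)
    if (length(bad))
      stop("malformed atom line in '", path, "' at line ", i + 1L + bad[1L])
    xyz <- t(vapply(tok, function(t)
      suppressWarnings(as.numeric(t[2:4])), numeric(3)))
    if (anyNA(xyz))
      stop("non-numeric coordinate in '", path, "' in block at line ", i)
    blocks[[length(blocks) + 1L]] <- list(
      elements = vapply(tok, `[[`, character(1), 1L),
      coords = xyz, comment = comment, line = i)
    i <- i + 2L + nat
  }
  if (!length(blocks)) stop("no geometry blocks found in '", path, "'")
  blocks
}

# comment-line energy: "E= <value> <unit>"; optional "id=<name>"
parse_xyz_comment <- function(comment) {
  en <- regmatches(comment,
                   regexec("E=\\s*([-+0-9.eE]+)\\s+(\\S+)", comment))[[1L]]
  id <- regmatches(comment, regexec("id=(\\S+)", comment))[[1L]]
  list(energy = if (length(en) == 3L) as.numeric(en[2L]) else NA_real_,
       unit = if (length(en) == 3L) en[3L] else NA_character_,
       id = if (length(id) == 2L) id[2L] else NA_character_)
}

read_energy_sidecar <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("conformer_id", "energy", "unit")
  if (!all(need %in% names(tab)))
    stop("energy sidecar '", path, "' must have columns ",
         paste(need, collapse = ", "))
  tab
}

#' Load a conformer ensemble from disk
#'
#' Reads a multi-conformer geometry file. Energies must be present either
#' in-file (XYZ comment line `E= <value> <unit>`, SDF property field) or in a
#' sidecar CSV with columns `conformer_id, energy, unit`; a missing energy is
#' an error, never a silent zero. Units must be declared (`kJ/mol` or
#' `hartree`) and are never guessed from magnitude. Energies are re-referenced
#' so the ensemble minimum is 0 kJ/mol.
#'
#' @param path Path to the geometry file.
#' @param format One of `"xyz-multi"` (multi-block XYZ), `"sdf"` (requires the
#'   ChemmineR package), `"csv-coords"` (long CSV with columns
#'   `conformer_id, atom_index, element, x, y, z`).
#' @param molecule_id,candidate_id,ff_tag Identifying strings stored on the
#'   ensemble.
#' @param energy_sidecar Optional path to the sidecar energy CSV.
#' @param sdf_energy_field Name of the SDF property holding the energy
#'   (value in kJ/mol).
#' @return An [ensemble()].
#' @export
load_ensemble <- function(path,
                          format = c("xyz-multi", "sdf", "csv-coords"),
                          molecule_id = "", candidate_id = "", ff_tag = "",
                          energy_sidecar = NULL,
                          sdf_energy_field = "rel_energy_kjmol") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  geo <- switch(format,
    "xyz-multi" = {
      blocks <- parse_xyz_blocks(readLines(path, warn = FALSE), path)
      lapply(seq_along(blocks), function(k) {
        b <- blocks[[k]]
        meta <- parse_xyz_comment(b$comment)
        list(id = if (!is.na(meta$id)) meta$id else sprintf("conf_%03d", k),
             elements = b$elements, coords = b$coords,
             energy = meta$energy, unit = meta$unit)
      })
    },
    "sdf" = {
      if (!requireNamespace("ChemmineR", quietly = TRUE))
        stop("SDF input requires the ChemmineR package")
      sdfs <- ChemmineR::read.SDFset(path)
      lapply(seq_along(ChemmineR::cid(sdfs)), function(k) {
        sdf <- sdfs[[k]]
        ab <- ChemmineR::atomblock(sdf)
        props <- ChemmineR::datablock(sdf)
        en <- if (sdf_energy_field %in% names(props))
          as.numeric(props[[sdf_energy_field]]) else NA_real_
        list(id = sprintf("conf_%03d", k),
             elements = sub("_.*$", "", rownames(ab)),
             coords = unname(ab[, 1:3, drop = FALSE]),
             energy = en,
             unit = if (is.na(en)) NA_character_ else "kJ/mol")
      })
    },
    "csv-coords" = {
      tab <- utils::read.csv(path, stringsAsFactors = FALSE)
      need <- c("conformer_id", "atom_index", "element", "x", "y", "z")
      if (!all(need %in% names(tab)))
        stop("csv-coords '", path, "' must have columns ",
             paste(need, collapse = ", "))
      lapply(split(tab, factor(tab$conformer_id,
                               levels = unique(tab$conformer_id))),
             function(d) {
               d <- d[order(d$atom_index), ]
               list(id = d$conformer_id[1L], elements = d$element,
                    coords = as.matrix(d[, c("x", "y", "z")]),
                    energy = NA_real_, unit = NA_character_)
             })
    })
  nat <- vapply(geo, function(g) nrow(g$coords), integer(1))
  if (length(unique(nat)) != 1L)
    stop("inconsistent atom counts across conformers in '", path, "': ",
         paste(unique(nat), collapse = " vs "))
  if (!is.null(energy_sidecar)) {
    side <- read_energy_sidecar(energy_sidecar)
    for (k in seq_along(geo)) {
      row <- match(geo[[k]]$id, side$conformer_id)
      if (is.na(row))
        stop("conformer '", geo[[k]]$id, "' has no row in energy sidecar '",
             energy_sidecar, "'")
      geo[[k]]$energy <- side$energy[row]
      geo[[k]]$unit <- side$unit[row]
    }
  }
  missing_e <- vapply(geo, function(g) is.na(g$energy), logical(1))
  if (any(missing_e))
    stop("missing energy for conformer(s) ",
         paste(vapply(geo[missing_e], `[[`, character(1), "id"),
               collapse = ", "),
         " (energies are required in-file or via a sidecar; never defaulted)")
  confs <- lapply(geo, function(g)
    conformer(g$id, g$elements, g$coords,
              energy_to_kjmol(g$energy, g$unit), ff_tag = ff_tag))
  ensemble(confs, molecule_id, candidate_id, ff_tag)
}

#' Write an ensemble as multi-conformer XYZ
#'
#' Inverse of [load_ensemble()] for the `xyz-multi` format; energies are
#' written on the comment line as `id=<id> E= <kJ/mol> kJ/mol`.
#' @param e An [ensemble()].
#' @param path Output path.
#' @export
write_xyz <- function(e, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in e$conformers) {
    writeLines(as.character(nrow(cf$coords)), con)
    writeLines(sprintf("id=%s E= %.10g kJ/mol", cf$id, cf$rel_energy), con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", cf$elements,
                       cf$coords[, 1], cf$coords[, 2], cf$coords[, 3]), con)
  }
  invisible(path)
}

## ---- curation ------------------------------------------------------------

#' Energy-window filter
#'
#' Keeps conformers with relative energy at or below `cutoff` (inclusive, so
#' boundary conformers are never trimmed). Ordering is preserved and the
#' global minimum always survives.
#'
#' @param e An [ensemble()].
#' @param cutoff Energy cutoff in kJ/mol (> 0).
#' @return The filtered [ensemble()].
#' @export
apply_energy_window <- function(e, cutoff) {
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  subset_ensemble(e, rel_energies(e) <= cutoff)
}

#' Deduplication configuration
#'
#' @param method Geometric criterion: `"MAD"` (maximum atom deviation) or
#'   `"RMSD"`.
#' @param geom_threshold Duplicate threshold in Angstrom (> 0).
#' @param energy_cutoff Energy window in kJ/mol used by the curation commands
#'   (> 0); [deduplicate()] itself uses only the geometric fields.
#' @param atom_subset `"heavy"` (non-hydrogen; default) or `"all"`.
#' @export
dedup_config <- function(method = c("MAD", "RMSD"), geom_threshold = 0.5,
                         energy_cutoff = 12, atom_subset = c("heavy", "all")) {
  method <- match.arg(method)
  atom_subset <- match.arg(atom_subset)
  if (geom_threshold <= 0) stop("geom_threshold must be > 0")
  if (energy_cutoff <= 0) stop("energy_cutoff must be > 0")
  structure(list(method = method, geom_threshold = geom_threshold,
                 energy_cutoff = energy_cutoff, atom_subset = atom_subset),
            class = "dedup_config")
}

subset_indices <- function(elements, atom_subset) {
  idx <- if (atom_subset == "heavy") which(elements != "H")
         else seq_along(elements)
  if (length(idx) == 0L)
    stop("atom subset '", atom_subset, "' is empty")
  idx
}

#' Least-squares superposition of two conformers
#'
#' Kabsch (SVD) optimal rigid-body superposition of `b` onto `a` over the
#' chosen atom subset, returning both deviation statistics computed over the
#' same subset after alignment: `rmsd`, the root-mean-square per-atom
#' deviation, and `mad`, the maximum per-atom deviation (so `rmsd <= mad`
#' always).
#'
#' @param a,b [conformer()] objects with identical atom ordering.
#' @param atom_subset `"heavy"` or `"all"`.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the aligned
#'   coordinates are `b %*% rotation + translation`), `rmsd` and `mad` in
#'   Angstrom.
#' @export
superpose <- function(a, b, atom_subset = c("heavy", "all")) {
  atom_subset <- match.arg(atom_subset)
  if (length(a$elements) != length(b$elements) ||
      !all(a$elements == b$elements))
    stop("conformers must share atom ordering")
  idx <- subset_indices(a$elements, atom_subset)
  P <- a$coords[idx, , drop = FALSE]
  Q <- b$coords[idx, , drop = FALSE]
  if (nrow(P) < 3L) stop("degenerate alignment: fewer than 3 subset atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (qr(Pc)$rank < 2L)
    stop("degenerate alignment: subset atoms are collinear")
  s <- svd(crossprod(Qc, Pc))           # covariance of centered b vs a
  d <- sign(det(s$u %*% t(s$v)))        # proper rotation only
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  aligned <- Qc %*% R
  dev <- sqrt(rowSums((aligned - Pc)^2))
  list(rotation = R, translation = cp - as.numeric(cq %*% R),
       rmsd = sqrt(mean(dev^2)), mad = max(dev))
}

pair_distance <- function(a, b, cfg) {
  s <- superpose(a, b, cfg$atom_subset)
  if (cfg$method == "MAD") s$mad else s$rmsd
}

#' Remove redundant conformers
#'
#' Greedy elimination in ascending energy order (ties broken by input order):
#' a conformer is discarded iff its MAD or RMSD distance to an
#' already-retained conformer is below `cfg$geom_threshold`. The global
#' minimum is always retained; output ordering is ascending energy. Because
#' `rmsd <= mad` for every pair, MAD declares duplicates less often and
#' retains at least as many conformers as RMSD at an equal threshold.
#'
#' @param e An [ensemble()].
#' @param cfg A [dedup_config()].
#' @return The deduplicated [ensemble()].
#' @export
deduplicate <- function(e, cfg) {
  stopifnot(inherits(cfg, "dedup_config"))
  ord <- order(rel_energies(e))         # stable: ties keep input order
  kept <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (j in kept) {
      if (pair_distance(e$conformers[[j]], e$conformers[[i]], cfg) <
          cfg$geom_threshold) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, i)
  }
  subset_ensemble(e, kept)
}

## ---- Boltzmann weighting -------------------------------------------------

#' Boltzmann population weights
#'
#' `w_i = exp(-E_i/RT) / sum_j exp(-E_j/RT)` with `R = 8.3145` J/(K mol),
#' computed with the max-shift trick so arbitrarily large energy gaps neither
#' overflow nor underflow to an all-zero vector.
#'
#' @param e An [ensemble()], or a (optionally named) numeric vector of
#'   relative energies in kJ/mol.
#' @param temperature Temperature in K (default 298).
#' @return Object of class `boltzmann_weights`: list with `weights` (named
#'   numeric, sums to 1) and `temperature`.
#' @export
boltzmann_weights <- function(e, temperature = 298) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  en <- if (inherits(e, "ensemble")) rel_energies(e) else e
  if (!all(is.finite(en))) stop("energies must be finite")
  x <- -(en * 1000) / (GAS_CONSTANT * temperature)
  x <- x - max(x)
  w <- exp(x) / sum(exp(x))
  if (is.null(names(w))) names(w) <- as.character(seq_along(w))
  structure(list(weights = w, temperature = temperature),
            class = "boltzmann_weights")
}

## ---- dihedrals -----------------------------------------------------------

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Signed dihedral angle
#'
#' Standard IUPAC signed torsion over four atoms, in degrees in the range
#' (-180, 180].
#'
#' @param x A [conformer()] or an N x 3 coordinate matrix.
#' @param atoms Integer vector of four distinct 1-based atom indices.
#' @return Angle in degrees.
#' @export
measure_dihedral <- function(x, atoms) {
  coords <- if (inherits(x, "conformer")) x$coords else as.matrix(x)
  if (length(atoms) != 4L || anyDuplicated(atoms))
    stop("atoms must be 4 distinct indices")
  if (any(atoms < 1L) || any(atoms > nrow(coords)))
    stop("atom index outside 1..", nrow(coords))
  p <- coords[atoms, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
    stop("collinear atom triple: dihedral undefined")
  ang <- atan2(sum(cross3(n1, n2) * b2 / sqrt(sum(b2^2))), sum(n1 * n2)) *
    180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}
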