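# Ensemble curation: loading, energy window, superposition, deduplication,
# Boltzmann weighting, dihedrals.

write_tmp_xyz <- function(blocks) {
  path <- withr::local_tempfile(fileext = ".xyz",
                                .local_envir = parent.frame())
  writeLines(unlist(blocks), path)
  path
}

xyz_block <- function(n, comment, atoms) c(as.character(n), comment, atoms)

test_that("multi-XYZ loading re-references energies and validates structure", {
  path <- write_tmp_xyz(list(
    xyz_block(3, "id=a E= 3.1 kJ/mol",
              c("C 0 0 0", "C 1.5 0 0", "O 2.0 1.4 0")),
    xyz_block(3, "id=b E= 0.0 kJ/mol",
              c("C 0 0 0", "C 1.5 0 0", "O 2.2 1.2 0.3"))))
  e <- load_ensemble(path, "xyz-multi")
  expect_s3_class(e, "ensemble")
  expect_length(e, 2)
  expect_equal(unname(sort(rel_energies(e))), c(0, 3.1))
  expect_equal(min(rel_energies(e)), 0)

  # inconsistent atom count is a structural error
  bad <- write_tmp_xyz(list(
    xyz_block(3, "E= 0 kJ/mol", c("C 0 0 0", "C 1.5 0 0", "O 2 1.4 0")),
    xyz_block(2, "E= 1 kJ/mol", c("C 0 0 0", "C 1.5 0 0"))))
  expect_error(load_ensemble(bad, "xyz-multi"), "inconsistent atom counts")

  # a missing energy is an explicit error, never a default zero
  noe <- write_tmp_xyz(list(
    xyz_block(2, "first conformer", c("C 0 0 0", "C 1.5 0 0"))))
  expect_error(load_ensemble(noe, "xyz-multi"), "missing energy")

  # malformed coordinates name the offending block
  garb <- write_tmp_xyz(list(
    xyz_block(2, "E= 0 kJ/mol", c("C 0 0 zero", "C 1.5 0 0"))))
  expect_error(load_ensemble(garb, "xyz-multi"), "non-numeric")
})

test_that("sidecar hartree energies convert to relative kJ/mol", {
  path <- write_tmp_xyz(list(
    xyz_block(2, "id=a", c("C 0 0 0", "C 1.5 0 0")),
    xyz_block(2, "id=b", c("C 0 0 0", "C 1.52 0.1 0"))))
  side <- withr::local_tempfile(fileext = ".csv")
  # hand conversion: (-154.1 - -154.102) * 2625.499 = 5.250998 kJ/mol
  write.csv(data.frame(conformer_id = c("a", "b"),
                       energy = c(-154.102, -154.100),
                       unit = "hartree"), side, row.names = FALSE)
  e <- load_ensemble(path, "xyz-multi", energy_sidecar = side)
  expect_equal(unname(rel_energies(e)), c(0, 0.002 * 2625.499),
               tolerance = 1e-9)
  # undeclared unit is rejected, never guessed
  write.csv(data.frame(conformer_id = c("a", "b"), energy = c(0, 1),
                       unit = "furlongs"), side, row.names = FALSE)
  expect_error(load_ensemble(path, "xyz-multi", energy_sidecar = side),
               "unknown energy unit")
})

test_that("XYZ write/load round-trips geometry and energies", {
  set.seed(42)
  confs <- lapply(1:3, function(i) random_conformer(paste0("c", i),
                                                    energy = i - 1))
  e <- ensemble(confs, "mol", "cand", "MMFF")
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(e, path)
  e2 <- load_ensemble(path, "xyz-multi")
  expect_equal(conformer_ids(e2), conformer_ids(e))
  expect_equal(rel_energies(e2), rel_energies(e), tolerance = 1e-8)
  expect_equal(e2$conformers[[2]]$coords, e$conformers[[2]]$coords,
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("energy window is inclusive, keeps the minimum, and is monotone", {
  set.seed(1)
  confs <- Map(function(i, en) random_conformer(paste0("c", i), energy = en),
               1:4, c(0, 11.9, 12, 12.1))
  e <- ensemble(confs)
  expect_length(apply_energy_window(e, 12), 3)   # boundary kept
  expect_length(apply_energy_window(e, 0.5), 1)  # minimum always survives
  expect_error(apply_energy_window(e, 0), "> 0")

  # retained(c1) is a subset of retained(c2) for c1 < c2, random ensembles
  for (rep in 1:20) {
    confs <- lapply(1:15, function(i)
      random_conformer(paste0("c", i), energy = runif(1, 0, 30)))
    e <- ensemble(confs)
    cuts <- sort(runif(2, 1, 30))
    lo <- conformer_ids(apply_energy_window(e, cuts[1]))
    hi <- conformer_ids(apply_energy_window(e, cuts[2]))
    expect_true(all(lo %in% hi))
  }
})

test_that("superposition removes rigid motion and matches the analytic case", {
  set.seed(7)
  a <- random_conformer("a", 10)
  # pure translation
  b <- conformer("b", a$elements, sweep(a$coords, 2, c(1, 2, 3), `+`), 0)
  s <- superpose(a, b, "all")
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  expect_equal(s$mad, 0, tolerance = 1e-9)
  # random proper rotation + translation
  b <- conformer("b", a$elements, rigid_move(a$coords), 0)
  s <- superpose(a, b, "all")
  expect_equal(s$rmsd, 0, tolerance = 1e-9)

  # one atom displaced along the line to the centroid of a large anchor set:
  # with many anchors the alignment shift is ~d/N; test against bio3d
  n <- 40
  a <- random_conformer("a", n)
  coords <- a$coords
  coords[5, ] <- coords[5, ] + c(0.8, 0, 0)
  b <- conformer("b", a$elements, rigid_move(coords), 0)
  s <- superpose(a, b, "all")
  o <- bio3d_rmsd_mad(a, b)
  expect_equal(s$rmsd, o$rmsd, tolerance = 1e-6)
  expect_equal(s$mad, o$mad, tolerance = 1e-6)
  # the 0.8 A displacement is recovered up to the ~1/N centroid/rotation
  # relaxation of the best fit
  expect_equal(s$mad, 0.8, tolerance = 0.1)
  expect_equal(s$rmsd, 0.8 / sqrt(n), tolerance = 0.1)
})

test_that("rmsd <= mad for every pair and both are rigid-motion invariant", {
  set.seed(11)
  for (rep in 1:25) {
    a <- random_conformer("a", 12)
    b <- conformer("b", a$elements,
                   a$coords + matrix(rnorm(36, sd = 0.3), ncol = 3), 0)
    s <- superpose(a, b, "all")
    expect_lte(s$rmsd, s$mad + 1e-12)
    # common rigid motion applied to both leaves rmsd/mad unchanged
    R <- random_rotation(); t <- rnorm(3, sd = 4)
    a2 <- conformer("a", a$elements, rigid_move(a$coords, R, t), 0)
    b2 <- conformer("b", b$elements, rigid_move(b$coords, R, t), 0)
    s2 <- superpose(a2, b2, "all")
    expect_equal(s2$rmsd, s$rmsd, tolerance = 1e-9)
    expect_equal(s2$mad, s$mad, tolerance = 1e-9)
  }
})

test_that("degenerate alignments are rejected", {
  line <- conformer("l", rep("C", 4),
                    cbind(seq(0, 4.5, length.out = 4), 0, 0), 0)
  expect_error(superpose(line, line, "all"), "collinear")
  hs <- conformer("h", c("C", "C", "H", "H", "H"),
                  matrix(rnorm(15), ncol = 3), 0)
  expect_error(superpose(hs, hs, "heavy"), "fewer than 3")
})

test_that("deduplication follows the greedy ascending-energy contract", {
  set.seed(3)
  # bitwise-identical geometries collapse to one
  a <- random_conformer("a", 8, energy = 0)
  b <- conformer("b", a$elements, a$coords, 1)
  e <- ensemble(list(a, b))
  cfg <- dedup_config("MAD", 0.5, atom_subset = "all")
  expect_equal(conformer_ids(deduplicate(e, cfg)), "a")

  # the lowest-energy conformer always survives; output is ascending energy
  for (rep in 1:10) {
    confs <- lapply(1:8, function(i) {
      base <- matrix(rnorm(24, sd = 1.5), ncol = 3)
      conformer(paste0("c", i), rep("C", 8), base, runif(1, 0, 10))
    })
    e <- ensemble(confs)
    d <- deduplicate(e, cfg)
    expect_equal(names(which.min(rel_energies(e))), conformer_ids(d)[1])
    expect_false(is.unsorted(rel_energies(d)))
    # idempotence
    d2 <- deduplicate(d, cfg)
    expect_equal(conformer_ids(d2), conformer_ids(d))
  }
})

test_that("MAD retains at least as many conformers as RMSD", {
  set.seed(5)
  for (rep in 1:10) {
    base <- matrix(rnorm(30, sd = 1.5), ncol = 3)
    confs <- lapply(1:10, function(i)
      conformer(paste0("c", i), rep("C", 10),
                base + matrix(rnorm(30, sd = 0.25), ncol = 3),
                runif(1, 0, 10)))
    e <- ensemble(confs)
    n_mad <- length(deduplicate(e, dedup_config("MAD", 0.5,
                                                atom_subset = "all")))
    n_rmsd <- length(deduplicate(e, dedup_config("RMSD", 0.5,
                                                 atom_subset = "all")))
    expect_gte(n_mad, n_rmsd)
  }
})

test_that("Boltzmann weights match analytic values and behave at T limits", {
  # equal energies: uniform
  w <- boltzmann_weights(c(a = 0, b = 0))
  expect_equal(unname(w$weights), c(0.5, 0.5))
  # Delta-E = RT ln 2 at 298 K: weights 2/3, 1/3
  dE <- 8.3145 * 298 * log(2) / 1000
  w <- boltzmann_weights(c(a = 0, b = dE))
  expect_equal(unname(w$weights), c(2 / 3, 1 / 3), tolerance = 1e-9)
  # 50 kJ/mol gap: minor weight below 2e-9, no overflow
  w <- boltzmann_weights(c(a = 0, b = 50))
  expect_lt(w$weights[["b"]], 2e-9)
  expect_equal(sum(w$weights), 1, tolerance = 1e-9)
  # T limits
  en <- c(a = 0, b = 3, c = 7)
  w_hot <- boltzmann_weights(en, temperature = 1e9)
  expect_equal(unname(w_hot$weights), rep(1 / 3, 3), tolerance = 1e-6)
  w_cold <- boltzmann_weights(en, temperature = 1e-3)
  expect_equal(w_cold$weights[["a"]], 1)
  expect_error(boltzmann_weights(en, temperature = 0), "> 0")
})

test_that("dihedrals follow the signed IUPAC convention", {
  expect_equal(measure_dihedral(torsion_points(0), 1:4), 0,
               tolerance = 1e-9)
  expect_equal(measure_dihedral(torsion_points(180), 1:4), 180,
               tolerance = 1e-9)
  expect_equal(measure_dihedral(torsion_points(60), 1:4), 60,
               tolerance = 1e-9)
  expect_equal(measure_dihedral(torsion_points(-60), 1:4), -60,
               tolerance = 1e-9)
  # collinear triple is a geometric error
  lin <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(measure_dihedral(lin, 1:4), "collinear")
  expect_error(measure_dihedral(torsion_points(60), c(1, 1, 2, 3)),
               "distinct")
})
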