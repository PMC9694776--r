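# Synthetic-data generator: determinism, geometric structure, ground-truth
# completeness, statistical faithfulness, round-trip through the file
# formats.

test_that("scaffolds are deterministic per seed and seed-sensitive", {
  s1 <- make_scaffold(12, 101)
  s2 <- make_scaffold(12, 101)
  expect_identical(s1$coords, s2$coords)
  s3 <- make_scaffold(12, 102)
  expect_false(isTRUE(all.equal(s1$coords, s3$coords)))
  # chain geometry: 1.5 A bonds, self-avoiding
  bonds <- sqrt(rowSums((s1$coords[-1, ] - s1$coords[-12, ])^2))
  expect_equal(bonds, rep(1.5, 11), tolerance = 1e-9)
  d <- as.matrix(dist(s1$coords))
  expect_true(all(d[abs(row(d) - col(d)) > 1] > 1.2))
  expect_equal(s1$elements, rep(c("C", "H"), 6))
  # n_atoms = 4: exactly one dihedral
  s4 <- make_scaffold(4, 5)
  expect_equal(nrow(s4$coords), 4)
  expect_silent(measure_dihedral(s4, 1:4))
  expect_error(make_scaffold(3, 1), ">= 4")
})

test_that("ensembles realize the requested rotamer states and inject
           duplicates", {
  spec <- fixture_spec(n_conformers = 9, n_couplings = 2, perturbation = 0,
                      torsion_jitter = 0, seed = 7)
  sc <- make_scaffold(8, 7)
  made <- make_ensemble(sc, spec)
  expect_length(made$ensemble, 9)
  # measured torsions equal the nominal states when jitter and noise are off
  expect_equal(made$torsions, made$states, tolerance = 1e-6)
  expect_true(all(made$states %in% c(-60, 60, 180)))
  # 9 conformers over 2 bonds cover all 9 rotamer combinations
  expect_equal(nrow(unique(made$states)), 9)

  # duplicate injection: dedup returns the duplicate-free count
  spec_d <- fixture_spec(n_conformers = 5, n_couplings = 1, perturbation = 0,
                         torsion_jitter = 0, duplicates = 2, seed = 8)
  made_d <- make_ensemble(make_scaffold(8, 8), spec_d)
  expect_length(made_d$ensemble, 7)
  dd <- deduplicate(made_d$ensemble,
                    dedup_config("MAD", 0.3, atom_subset = "all"))
  expect_lte(length(dd), 5)

  # pure Cartesian jitter without rotamers stays below the duplicate
  # threshold, so MAD-0.5 dedup collapses to one conformer
  spec_j <- fixture_spec(n_conformers = 6, perturbation = 0.02,
                         rotamers = FALSE, seed = 9)
  made_j <- make_ensemble(make_scaffold(10, 9), spec_j)
  for (i in 1:5) for (j in (i + 1):6) {
    s <- superpose(made_j$ensemble$conformers[[i]],
                   made_j$ensemble$conformers[[j]], "all")
    expect_lt(s$mad, 0.5)
  }
  expect_length(deduplicate(made_j$ensemble,
                            dedup_config("MAD", 0.5, atom_subset = "all")),
                1)
})

test_that("fixtures are bitwise deterministic per seed", {
  f1 <- make_fixture(fixture_spec(seed = 33))
  f2 <- make_fixture(fixture_spec(seed = 33))
  expect_identical(f1$shieldings, f2$shieldings)
  expect_identical(f1$exp$shifts$delta_exp_ppm, f2$exp$shifts$delta_exp_ppm)
  expect_identical(f1$ensembles$isomer_001$conformers[[3]]$coords,
                   f2$ensembles$isomer_001$conformers[[3]]$coords)
  f3 <- make_fixture(fixture_spec(seed = 34))
  expect_false(identical(f1$exp$shifts$delta_exp_ppm,
                         f3$exp$shifts$delta_exp_ppm))
})

test_that("ground truth stores every averaged intermediate", {
  fx <- make_fixture(fixture_spec(seed = 40))
  for (cand in names(fx$ensembles)) {
    w <- boltzmann_weights(fx$ensembles[[cand]])
    # stored averaged sigma equals an independent weighted-mean recomputation
    tbl <- fx$shieldings[[cand]]
    oracle <- vapply(sort(unique(tbl$atom_index)), function(a) {
      rows <- tbl[tbl$atom_index == a, ]
      sum(w$weights[rows$conformer_id] * rows$sigma_ppm)
    }, numeric(1))
    expect_equal(fx$truth$sigma_avg[[cand]]$sigma_ppm, oracle,
                 tolerance = 1e-9)
    expect_equal(fx$truth$weights_true[[cand]], w$weights,
                 tolerance = 1e-12)
  }
  expect_true(fx$truth$true_candidate %in% names(fx$ensembles))
  expect_equal(fx$truth$seed, 40)
})

test_that("zero noise and zero inflation make candidates indistinguishable;
           strong inflation makes the true candidate certain", {
  sp0 <- fixture_spec(noise_scale = 0, inflate_location = 0, seed = 50)
  fx0 <- make_fixture(sp0)
  res0 <- run_assignment(fx0$ensembles, fx0$shieldings, fx0$exp, fx0$ref,
                         assignment_config(j_scale = "identity"),
                         couplings_calc = fx0$couplings_calc)
  expect_equal(unname(res0$P_combined), rep(0.5, 2), tolerance = 1e-9)

  sp5 <- fixture_spec(noise_scale = 0, inflate_location = 5, seed = 51)
  fx5 <- make_fixture(sp5)
  res5 <- run_assignment(fx5$ensembles, fx5$shieldings, fx5$exp, fx5$ref,
                         assignment_config(j_scale = "identity"),
                         couplings_calc = fx5$couplings_calc)
  expect_gt(res5$P_combined[[fx5$truth$true_candidate]], 0.99)
})

test_that("the generator's error sampler follows the configured t law", {
  em <- error_model("jdp4-2019")
  set.seed(1234)
  draws <- mixjdp4:::rt_channel(1e4, em$C)
  ks <- ks.test(draws / em$C$sigma, "pt", df = em$C$nu)
  expect_gt(ks$p.value, 0.05)
  # scale multiplier scales the spread
  set.seed(1234)
  wide <- mixjdp4:::rt_channel(1e4, em$C, scale_mult = 3)
  expect_equal(wide, draws * 3, tolerance = 1e-12)
})

test_that("full-pipeline true-candidate errors have the configured scale", {
  # regression on noisy experimental abscissae perturbs the exact t shape,
  # so assert calibrated moments rather than a sharp GOF at pipeline level
  errs <- c()
  for (s in 1:40) {
    fx <- make_fixture(fixture_spec(n_candidates = 1, rotamers = FALSE,
                                    conf_amp_H = 0, conf_amp_C = 0,
                                    seed = 600 + s))
    cand <- fx$truth$true_candidate
    pipe <- mixjdp4:::candidate_pipeline(
      cand, fx$ensembles[[cand]], fx$shieldings[[cand]],
      fx$couplings_calc[[cand]], fx$exp, fx$ref,
      assignment_config(ij_filter = FALSE, j_scale = "identity"))
    errs <- c(errs, pipe$errors$C)
  }
  em <- error_model("jdp4-2019")
  nu <- em$C$nu
  expect_equal(mean(errs), 0, tolerance = 0.4)
  expect_equal(sd(errs), em$C$sigma * sqrt(nu / (nu - 2)),
               tolerance = 0.35)
})

test_that("bundles round-trip through the plain-text formats", {
  spec <- fixture_spec(seed = 70)
  fx <- make_fixture(spec)
  dir <- withr::local_tempdir()
  write_fixture_bundle(fx, dir, spec = spec)
  expect_true(all(file.exists(file.path(dir, c(
    "isomer_001.xyz", "isomer_002.xyz", "isomer_001_shieldings.csv",
    "experimental_shifts.csv", "experimental_couplings.csv",
    "reference.json", "truth.json", "spec.json")))))
  back <- read_fixture_bundle(dir)
  expect_equal(names(back$ensembles), names(fx$ensembles))
  expect_equal(rel_energies(back$ensembles$isomer_002),
               rel_energies(fx$ensembles$isomer_002), tolerance = 1e-8)
  expect_equal(back$exp$shifts$delta_exp_ppm, fx$exp$shifts$delta_exp_ppm)
  expect_equal(back$exp$couplings$J_exp_hz, fx$exp$couplings$J_exp_hz)
  expect_equal(back$truth$true_candidate, fx$truth$true_candidate)
  # assignments from disk match assignments from memory
  cfg <- assignment_config(j_scale = "identity")
  r_mem <- run_assignment(fx$ensembles, fx$shieldings, fx$exp, fx$ref, cfg,
                          couplings_calc = fx$couplings_calc)
  r_dsk <- run_assignment(back$ensembles, back$shieldings, back$exp,
                          back$ref, cfg, couplings_calc = back$couplings_calc)
  expect_equal(r_dsk$P_combined, r_mem$P_combined, tolerance = 1e-6)
})

test_that("multi-force-field fixtures share one experiment", {
  fxm <- make_fixture_multiff(fixture_spec(seed = 80))
  expect_equal(names(fxm$per_ff), c("AMBER", "MM3", "MMFF"))
  expect_identical(fxm$per_ff$AMBER$exp$shifts$delta_exp_ppm,
                   fxm$per_ff$MMFF$exp$shifts$delta_exp_ppm)
  # ensembles differ across force fields
  expect_false(identical(
    fxm$per_ff$AMBER$ensembles$isomer_001$conformers[[1]]$coords,
    fxm$per_ff$MM3$ensembles$isomer_001$conformers[[1]]$coords))
  expect_equal(fxm$per_ff$AMBER$ensembles$isomer_001$ff_tag, "AMBER")
})
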