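# Synthetic, fully ground-truthed inputs: scaffold geometries, conformer
# ensembles with rotamer states, shieldings/couplings consistent with a known
# true stereoisomer, and matching experimental tables. Statistical stand-ins,
# not physical molecules: every number the pipeline computes has a stored
# truth.

#' Fixture specification
#'
#' Study conditions for one synthetic assignment problem. Defaults describe a
#' small flexible molecule measured on both channels: 2 candidates, 9
#' conformers (one per rotamer combination of the two rotatable coupling
#' bonds), 10 + 10 signals, 2 filtering-grade couplings, Cartesian jitter
#' 0.02 A (the scale of typical force-field geometry differences), an 8
#' kJ/mol energy spread, and wrong-candidate errors inflated by a 2-sigma
#' location shift per signal.
#'
#' @param n_candidates Number of candidate stereoisomers (>= 1).
#' @param n_conformers Conformers per ensemble.
#' @param n_H_signals,n_C_signals,n_couplings Observable counts.
#' @param perturbation Cartesian noise scale in Angstrom.
#' @param energy_spread Relative-energy range in kJ/mol (energies are drawn
#'   uniformly on `[0, energy_spread]`).
#' @param error_model Error-model profile for noise generation (see
#'   [error_model()]).
#' @param inflate_location Wrong-candidate location shift, in channel-sigma
#'   units, applied with a random sign per (candidate, signal).
#' @param inflate_scale Wrong-candidate error scale multiplier (>= 1).
#' @param karplus_profile Karplus profile linking dihedrals to couplings.
#' @param j_scale Coupling scaling profile the emitted per-conformer
#'   couplings are encoded for (the generator writes Fermi-contact-style
#'   values whose rescale recovers the Karplus coupling).
#' @param noise_target `"experimental"` (noise on experimental values; keeps
#'   true-candidate scaled errors on the configured t) or `"shieldings"`
#'   (noise on per-conformer shieldings; geometry-sensitivity tests).
#' @param noise_scale Multiplier on all injected noise (0 = noiseless).
#' @param rotamers Give conformers distinct rotamer states at -60/60/180
#'   degrees (TRUE) or keep the scaffold torsions (FALSE).
#' @param conf_amp_H,conf_amp_C Amplitude (ppm) of the rotamer-linked
#'   conformer-dependent shift offsets (what makes Boltzmann averaging and
#'   the iJ filter matter).
#' @param torsion_jitter Rotamer torsion jitter, degrees.
#' @param duplicates Number of exact geometric duplicates of the first
#'   conformer to inject (deduplication tests).
#' @param ff_tag Force-field tag written on generated conformers.
#' @param seed Integer seed; mandatory, recorded in all outputs. The
#'   generator uses R's Mersenne-Twister with inversion normals.
#' @export
fixture_spec <- function(n_candidates = 2L, n_conformers = 9L,
                         n_H_signals = 10L, n_C_signals = 10L,
                         n_couplings = 2L, perturbation = 0.02,
                         energy_spread = 8, error_model = "jdp4-2019",
                         inflate_location = 2, inflate_scale = 1,
                         karplus_profile = "classical",
                         j_scale = "identity",
                         noise_target = c("experimental", "shieldings"),
                         noise_scale = 1, rotamers = TRUE,
                         conf_amp_H = 0.2, conf_amp_C = 2,
                         torsion_jitter = 8, duplicates = 0L,
                         ff_tag = "MMFF", seed = 1L) {
  noise_target <- match.arg(noise_target)
  if (n_candidates < 1L || n_conformers < 1L || n_H_signals < 1L ||
      n_C_signals < 1L || n_couplings < 1L)
    stop("all counts must be >= 1")
  if (perturbation < 0 || energy_spread < 0 || noise_scale < 0)
    stop("perturbation, energy_spread and noise_scale must be >= 0")
  if (inflate_scale < 1) stop("inflate_scale must be >= 1")
  if (is.null(seed)) stop("a seed is mandatory (no wall-clock seeding)")
  structure(list(n_candidates = as.integer(n_candidates),
                 n_conformers = as.integer(n_conformers),
                 n_H_signals = as.integer(n_H_signals),
                 n_C_signals = as.integer(n_C_signals),
                 n_couplings = as.integer(n_couplings),
                 perturbation = perturbation, energy_spread = energy_spread,
                 error_model = error_model,
                 inflate_location = inflate_location,
                 inflate_scale = inflate_scale,
                 karplus_profile = karplus_profile, j_scale = j_scale,
                 noise_target = noise_target, noise_scale = noise_scale,
                 rotamers = rotamers, conf_amp_H = conf_amp_H,
                 conf_amp_C = conf_amp_C, torsion_jitter = torsion_jitter,
                 duplicates = as.integer(duplicates), ff_tag = ff_tag,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

set_fixture_seed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
}

# place atom D given A, B, C: bond length d to C, bond angle theta at C,
# torsion phi for A-B-C-D (NeRF construction)
place_atom <- function(A, B, C, d, theta, phi) {
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(B - A, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  t <- theta * pi / 180; p <- phi * pi / 180
  as.numeric(C + cbind(bc, m, n) %*%
               c(-d * cos(t), d * sin(t) * cos(p), d * sin(t) * sin(p)))
}

#' Build a scaffold chain
#'
#' A self-avoiding 3-D chain with 1.5 A bonds, tetrahedral bond angles, and
#' near-trans backbone torsions with seed-dependent jitter, so every internal
#' bond is rotatable. Elements alternate C (odd positions) and H (even
#' positions). Deterministic per seed.
#'
#' @param n_atoms Chain length (>= 4; `n_atoms = 4` has exactly one
#'   dihedral).
#' @param seed Integer seed.
#' @return A [conformer()].
#' @export
make_scaffold <- function(n_atoms, seed) {
  if (n_atoms < 4L) stop("n_atoms must be >= 4")
  set_fixture_seed(seed)
  for (attempt in 1:50) {
    coords <- matrix(0, n_atoms, 3)
    coords[2, ] <- c(1.5, 0, 0)
    coords[3, ] <- place_atom(c(0, 0, 1), coords[1, ], coords[2, ],
                              1.5, 109.47, 0)
    if (n_atoms > 3L) {
      tors <- 180 + stats::rnorm(n_atoms - 3L, 0, 10)
      for (i in 4:n_atoms)
        coords[i, ] <- place_atom(coords[i - 3L, ], coords[i - 2L, ],
                                  coords[i - 1L, ], 1.5, 109.47,
                                  tors[i - 3L])
    }
    d <- as.matrix(stats::dist(coords))
    nb <- abs(row(d) - col(d)) > 1L      # non-bonded pairs
    if (all(d[nb] > 1.2)) break          # self-avoiding
  }
  elements <- ifelse(seq_len(n_atoms) %% 2L == 1L, "C", "H")
  conformer("scaffold", elements, coords, 0)
}

# rotate atoms with index > pivot about the axis b -> c so that the torsion
# of `quad` becomes `target` degrees
set_torsion <- function(coords, quad, target) {
  b <- coords[quad[2L], ]; cc <- coords[quad[3L], ]
  current <- measure_dihedral(coords, quad)
  rotate_tail <- function(delta) {
    u <- cc - b; u <- u / sqrt(sum(u^2))
    th <- delta * pi / 180
    K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    out <- coords
    tail_idx <- (quad[3L] + 1L):nrow(coords)
    out[tail_idx, ] <- sweep(sweep(coords[tail_idx, , drop = FALSE], 2, cc)
                             %*% t(R), 2, cc, `+`)
    out
  }
  cand <- rotate_tail(target - current)
  if (angular_distance(measure_dihedral(cand, quad), target) > 1e-6)
    cand <- rotate_tail(current - target)
  cand
}

coupling_quads <- function(n_couplings) {
  lapply(seq_len(n_couplings), function(k) (4L * k - 3L):(4L * k))
}

#' Generate a conformer ensemble from a scaffold
#'
#' Each conformer gets one rotamer state (-60/60/180 degrees plus jitter) per
#' rotatable coupling bond, Cartesian noise at the perturbation scale, and a
#' uniform relative energy on `[0, energy_spread]` (energies are deliberately
#' independent of rotamer state: they stand in for force-field energy error).
#' Optionally injects exact duplicates of the first conformer.
#'
#' @param scaffold A [make_scaffold()] conformer.
#' @param spec A [fixture_spec()].
#' @param candidate_id Candidate id stamped on the ensemble.
#' @return List: `ensemble`, `torsions` (conformer x coupling matrix of true
#'   dihedrals, degrees) and `states` (nominal rotamer states).
#' @export
make_ensemble <- function(scaffold, spec, candidate_id = "isomer_001") {
  quads <- coupling_quads(spec$n_couplings)
  if (max(unlist(quads)) > nrow(scaffold$coords))
    stop("scaffold too short for ", spec$n_couplings, " couplings")
  n <- spec$n_conformers
  # rotamer-state combinations sampled without replacement (recycled past
  # 3^K), emulating a systematic rotamer search rather than random draws
  combos <- as.matrix(expand.grid(rep(list(c(-60, 60, 180)),
                                      spec$n_couplings)))
  pick <- rep_len(sample(nrow(combos)), n)
  states <- matrix(0, n, spec$n_couplings)
  torsions <- matrix(0, n, spec$n_couplings)
  confs <- vector("list", n + spec$duplicates)
  for (i in seq_len(n)) {
    coords <- scaffold$coords
    for (k in seq_len(spec$n_couplings)) {
      states[i, k] <- if (spec$rotamers) combos[pick[i], k]
                      else measure_dihedral(coords, quads[[k]])
      target <- states[i, k] +
        if (spec$rotamers) stats::rnorm(1, 0, spec$torsion_jitter) else 0
      coords <- set_torsion(coords, quads[[k]], target)
    }
    if (spec$perturbation > 0)
      coords <- coords + matrix(stats::rnorm(length(coords), 0,
                                             spec$perturbation),
                                ncol = 3)
    for (k in seq_len(spec$n_couplings))
      torsions[i, k] <- measure_dihedral(coords, quads[[k]])
    confs[[i]] <- conformer(sprintf("c%03d", i), scaffold$elements, coords,
                            stats::runif(1, 0, spec$energy_spread),
                            ff_tag = spec$ff_tag)
  }
  if (spec$duplicates > 0L) {
    for (j in seq_len(spec$duplicates)) {
      confs[[n + j]] <- conformer(sprintf("c%03d", n + j),
                                  scaffold$elements, confs[[1L]]$coords,
                                  stats::runif(1, 0, spec$energy_spread),
                                  ff_tag = spec$ff_tag)
      states <- rbind(states, states[1L, ])
      torsions <- rbind(torsions, torsions[1L, ])
    }
  }
  list(ensemble = ensemble(confs, molecule_id = "synthetic",
                           candidate_id = candidate_id,
                           ff_tag = spec$ff_tag),
       torsions = torsions, states = states)
}

# scaled t draw for one channel of an error model
rt_channel <- function(n, ch, scale_mult = 1) {
  ch$mu + ch$sigma * scale_mult * stats::rt(n, df = ch$nu)
}

# experiment-level context shared across force fields: true signal shifts,
# rotamer-linked offset loadings, solution rotamer states, wrong-candidate
# inflation draws, experimental noise
draw_experiment <- function(spec, candidates, true_candidate) {
  em <- error_model(spec$error_model)
  nH <- spec$n_H_signals; nC <- spec$n_C_signals; K <- spec$n_couplings
  base <- c(stats::runif(nH, 1, 8), stats::runif(nC, 10, 160))
  elem <- c(rep("H", nH), rep("C", nC))
  atoms <- c(2L * seq_len(nH), 2L * seq_len(nC) - 1L)
  amp <- ifelse(elem == "H", spec$conf_amp_H, spec$conf_amp_C)
  u <- stats::rnorm(nH + nC)
  bond_of <- (seq_len(nH + nC) - 1L) %% K + 1L
  solution <- sample(c(-60, 60, 180), K, replace = TRUE)
  sig <- ifelse(elem == "H", em$H$sigma, em$C$sigma)
  wrong <- list()
  for (cand in candidates) {
    if (cand == true_candidate) { wrong[[cand]] <- list(shift = rep(0, nH + nC),
                                                        jshift = rep(0, K)); next }
    sgn <- sample(c(-1, 1), nH + nC, replace = TRUE)
    extra <- sqrt(max(spec$inflate_scale^2 - 1, 0))
    wrong[[cand]] <- list(
      shift = spec$inflate_location * sig * sgn +
        sig * extra * stats::rnorm(nH + nC),
      jshift = spec$inflate_location * em$J$sigma *
        sample(c(-1, 1), K, replace = TRUE) +
        em$J$sigma * extra * stats::rnorm(K))
  }
  noise <- spec$noise_scale *
    c(rt_channel(nH, em$H), rt_channel(nC, em$C))
  jnoise <- spec$noise_scale * rt_channel(K, em$J)
  # regression truth: affine encoding of shifts into shieldings
  m_true <- c(H = stats::runif(1, 0.95, 1.1), C = stats::runif(1, 0.95, 1.1))
  b_true <- c(H = stats::runif(1, -0.5, 0.5), C = stats::runif(1, -3, 3))
  list(em = em, base = base, elem = elem, atoms = atoms, amp = amp, u = u,
       bond_of = bond_of, solution = solution, wrong = wrong,
       noise = noise, jnoise = jnoise, m_true = m_true, b_true = b_true)
}

#' Generate NMR observables for a set of candidate ensembles
#'
#' Per-conformer shieldings encode, affinely (slope/intercept stored in the
#' ground truth), signal shifts made of a per-signal base value plus a
#' rotamer-linked conformer-dependent offset — so Boltzmann averaging
#' matters — plus, for wrong candidates, the configured error inflation.
#' Experimental shifts are the true-candidate values at the solution rotamer
#' plus scaled Student-t noise; couplings come from the solution dihedrals
#' through the Karplus curve plus t noise, and per-conformer computed
#' couplings from each conformer's true dihedral (encoded for the configured
#' coupling-scaling profile).
#'
#' @param made Named list (per candidate) of [make_ensemble()] outputs.
#' @param spec A [fixture_spec()].
#' @param true_candidate Name of the ground-truth candidate.
#' @param ctx Experiment-level draws from an earlier call (internal; used to
#'   share one experiment across force fields).
#' @return List: `shieldings` (named list of shielding tables),
#'   `couplings_calc` (named list of per-conformer coupling tables), `exp`
#'   ([experimental_data()]), `ref` ([reference_standard()]) and `truth`.
#' @export
make_nmr_data <- function(made, spec, true_candidate = names(made)[1L],
                          ctx = NULL) {
  candidates <- names(made)
  if (is.null(ctx)) ctx <- draw_experiment(spec, candidates, true_candidate)
  K <- spec$n_couplings
  quads <- coupling_quads(K)
  ref <- reference_standard(31.9, 189.7,
                            "synthetic reference (fixture generator)")
  s0 <- ifelse(ctx$elem == "H", ref$sigma_H, ref$sigma_C)
  jp <- if (is.numeric(spec$j_scale)) spec$j_scale else
    switch(spec$j_scale, identity = c(a = 1, c = 0),
           "fc-b3lyp" = c(a = 0.9117, c = 0))
  shieldings <- list(); couplings_calc <- list()
  offsets <- list()
  for (cand in candidates) {
    ens <- made[[cand]]$ensemble
    tors <- made[[cand]]$torsions
    ids <- conformer_ids(ens)
    rows <- list()
    off <- matrix(0, length(ids), length(ctx$base))
    for (i in seq_along(ids)) {
      off[i, ] <- ctx$amp * ctx$u *
        cos((tors[i, ctx$bond_of] - ctx$solution[ctx$bond_of]) * pi / 180)
      delta_i <- ctx$base + off[i, ] + ctx$wrong[[cand]]$shift
      sigma_i <- s0 - (ctx$m_true[ctx$elem] * delta_i + ctx$b_true[ctx$elem])
      if (spec$noise_target == "shieldings")
        sigma_i <- sigma_i + spec$noise_scale *
          ifelse(ctx$elem == "H", ctx$em$H$sigma, ctx$em$C$sigma) *
          stats::rnorm(length(sigma_i))
      rows[[i]] <- data.frame(conformer_id = ids[i],
                              atom_index = ctx$atoms, element = ctx$elem,
                              sigma_ppm = sigma_i)
    }
    shieldings[[cand]] <- as_shielding_table(do.call(rbind, rows))
    offsets[[cand]] <- off
    jr <- expand.grid(conformer_id = ids, k = seq_len(K),
                      stringsAsFactors = FALSE)
    jr$pair_id <- sprintf("J%02d", jr$k)
    jtrue <- vapply(seq_len(nrow(jr)), function(r)
      karplus(tors[match(jr$conformer_id[r], ids), jr$k[r]],
              spec$karplus_profile) + ctx$wrong[[cand]]$jshift[jr$k[r]],
      numeric(1))
    jr$J_hz <- (jtrue - jp[["c"]]) / jp[["a"]]   # undo the pipeline rescale
    couplings_calc[[cand]] <- jr[, c("conformer_id", "pair_id", "J_hz")]
  }
  delta_exp <- ctx$base + ctx$amp * ctx$u + ctx$noise
  shifts <- data.frame(
    signal_id = sprintf("%s%02d", ctx$elem, seq_along(ctx$base)),
    element = ctx$elem,
    atoms = I(as.list(ctx$atoms)),
    delta_exp_ppm = delta_exp)
  j_exp <- pmax(karplus(ctx$solution, spec$karplus_profile) + ctx$jnoise, 0)
  couplings <- data.frame(pair_id = sprintf("J%02d", seq_len(K)),
                          h1 = vapply(quads, `[`, integer(1), 1L),
                          h2 = vapply(quads, `[`, integer(1), 4L),
                          dihedral = I(quads), J_exp_hz = j_exp,
                          filter = TRUE)
  exp <- experimental_data(shifts, couplings)
  truth <- list(true_candidate = true_candidate, seed = spec$seed,
                rng = "Mersenne-Twister/Inversion",
                delta_base = ctx$base, offset_loadings = ctx$u,
                offsets = offsets, solution_torsions = ctx$solution,
                m_true = ctx$m_true, b_true = ctx$b_true,
                wrong_shifts = ctx$wrong, exp_noise = ctx$noise,
                j_noise = ctx$jnoise,
                torsions = lapply(made, `[[`, "torsions"),
                weights_true = lapply(made, function(m)
                  boltzmann_weights(m$ensemble)$weights),
                sigma_avg = lapply(candidates, function(cand)
                  average_shieldings(shieldings[[cand]],
                                     boltzmann_weights(made[[cand]]$ensemble))))
  names(truth$sigma_avg) <- candidates
  list(shieldings = shieldings, couplings_calc = couplings_calc,
       exp = exp, ref = ref, truth = truth)
}

#' Generate a complete single-force-field fixture
#'
#' One call producing everything [run_assignment()] needs, with ground truth:
#' candidate ensembles (shared conformer geometries — candidates are
#' distinguished purely by their error structure), shieldings, per-conformer
#' couplings, experimental tables, and reference standard.
#'
#' @param spec A [fixture_spec()].
#' @return List `ensembles`, `shieldings`, `couplings_calc`, `exp`, `ref`,
#'   `truth`.
#' @export
make_fixture <- function(spec) {
  set_fixture_seed(spec$seed)
  n_atoms <- max(8L, 4L * spec$n_couplings, 2L * spec$n_H_signals,
                 2L * spec$n_C_signals)
  scaffold <- make_scaffold(n_atoms, spec$seed)
  candidates <- sprintf("isomer_%03d", seq_len(spec$n_candidates))
  true_candidate <- sample(candidates, 1L)
  made0 <- make_ensemble(scaffold, spec, candidate_id = candidates[1L])
  made <- lapply(candidates, function(cand) {
    m <- made0
    m$ensemble$candidate_id <- cand
    m
  })
  names(made) <- candidates
  nmr <- make_nmr_data(made, spec, true_candidate = true_candidate)
  ensembles <- lapply(made, `[[`, "ensemble")
  c(list(ensembles = ensembles), nmr)
}

#' Generate one experiment observed through several force fields
#'
#' Shares a single experimental data set (one physical reality) across
#' independent per-force-field conformer ensembles — each force field gets
#' its own rotamer populations, energies and geometric jitter — for testing
#' the multi-force-field averaging workflow.
#'
#' @param spec A [fixture_spec()].
#' @param ff_tags Force-field tags (default AMBER, MM3, MMFF).
#' @return List `per_ff` (named list of single-force-field bundles as from
#'   [make_fixture()], all sharing `exp`/`ref`), `exp`, `ref`, `truth`.
#' @export
make_fixture_multiff <- function(spec, ff_tags = c("AMBER", "MM3", "MMFF")) {
  set_fixture_seed(spec$seed)
  n_atoms <- max(8L, 4L * spec$n_couplings, 2L * spec$n_H_signals,
                 2L * spec$n_C_signals)
  scaffold <- make_scaffold(n_atoms, spec$seed)
  candidates <- sprintf("isomer_%03d", seq_len(spec$n_candidates))
  true_candidate <- sample(candidates, 1L)
  ctx <- draw_experiment(spec, candidates, true_candidate)
  per_ff <- list()
  shared <- NULL
  for (f in ff_tags) {
    sp <- spec; sp$ff_tag <- f
    made0 <- make_ensemble(scaffold, sp, candidate_id = candidates[1L])
    made <- lapply(candidates, function(cand) {
      m <- made0; m$ensemble$candidate_id <- cand; m
    })
    names(made) <- candidates
    nmr <- make_nmr_data(made, sp, true_candidate = true_candidate,
                         ctx = ctx)
    shared <- nmr
    per_ff[[f]] <- c(list(ensembles = lapply(made, `[[`, "ensemble")), nmr)
  }
  list(per_ff = per_ff, exp = shared$exp, ref = shared$ref,
       truth = shared$truth)
}

#' Write a fixture bundle to disk
#'
#' Emits exactly the plain-text formats the loading functions read —
#' multi-conformer XYZ per candidate, shielding and computed-coupling CSVs,
#' experimental shift and coupling CSVs, the reference standard, the spec and
#' the ground truth as JSON — so bundles double as format round-trip tests
#' and as ready-to-run worked examples.
#'
#' @param fx A [make_fixture()] bundle.
#' @param dir Output directory (created).
#' @param spec The [fixture_spec()] used (recorded in `spec.json`).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(fx, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cand in names(fx$ensembles)) {
    write_xyz(fx$ensembles[[cand]], file.path(dir, paste0(cand, ".xyz")))
    utils::write.csv(fx$shieldings[[cand]],
                     file.path(dir, paste0(cand, "_shieldings.csv")),
                     row.names = FALSE)
    utils::write.csv(fx$couplings_calc[[cand]],
                     file.path(dir, paste0(cand, "_couplings.csv")),
                     row.names = FALSE)
  }
  sh <- fx$exp$shifts
  utils::write.csv(data.frame(signal_id = sh$signal_id,
                              element = sh$element,
                              atom_indices = vapply(sh$atoms, paste,
                                                    character(1),
                                                    collapse = ";"),
                              delta_exp_ppm = sh$delta_exp_ppm),
                   file.path(dir, "experimental_shifts.csv"),
                   row.names = FALSE)
  cp <- fx$exp$couplings
  utils::write.csv(data.frame(pair_id = cp$pair_id, h1 = cp$h1, h2 = cp$h2,
                              dihedral_atoms = vapply(cp$dihedral, paste,
                                                      character(1),
                                                      collapse = ";"),
                              J_exp_hz = cp$J_exp_hz, filter = cp$filter),
                   file.path(dir, "experimental_couplings.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(sigma_H = fx$ref$sigma_H,
                            sigma_C = fx$ref$sigma_C,
                            provenance = fx$ref$provenance),
                       file.path(dir, "reference.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(fx$truth[c("true_candidate", "seed", "rng",
                                  "solution_torsions", "m_true", "b_true")],
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(spec))
    jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir Bundle directory.
#' @return The same structure as [make_fixture()] minus the full ground truth
#'   (only the serialized truth fields are restored).
#' @export
read_fixture_bundle <- function(dir) {
  xyz <- sort(list.files(dir, pattern = "^isomer_[0-9]+\\.xyz$"))
  if (!length(xyz)) stop("no candidate XYZ files found in ", dir)
  cands <- sub("\\.xyz$", "", xyz)
  ensembles <- lapply(cands, function(cand)
    load_ensemble(file.path(dir, paste0(cand, ".xyz")), "xyz-multi",
                  molecule_id = "synthetic", candidate_id = cand))
  names(ensembles) <- cands
  shieldings <- lapply(cands, function(cand)
    read_shieldings(file.path(dir, paste0(cand, "_shieldings.csv"))))
  names(shieldings) <- cands
  couplings_calc <- lapply(cands, function(cand)
    utils::read.csv(file.path(dir, paste0(cand, "_couplings.csv")),
                    stringsAsFactors = FALSE))
  names(couplings_calc) <- cands
  exp <- read_experimental(file.path(dir, "experimental_shifts.csv"),
                           file.path(dir, "experimental_couplings.csv"))
  rj <- jsonlite::read_json(file.path(dir, "reference.json"),
                            simplifyVector = TRUE)
  truth <- if (file.exists(file.path(dir, "truth.json")))
    jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  list(ensembles = ensembles, shieldings = shieldings,
       couplings_calc = couplings_calc, exp = exp,
       ref = reference_standard(rj$sigma_H, rj$sigma_C, rj$provenance),
       truth = truth)
}
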