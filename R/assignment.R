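# Whole-workflow orchestration: per-candidate pipeline, channel combination,
# multi-force-field averaging (mix-J-DP4), and result serialization.

#' Assignment configuration
#'
#' Defaults follow the recommended practice for force-field-geometry DP4-type
#' work: 12 kJ/mol energy window, MAD 0.5 A deduplication, 298 K, the
#' combined iJ/dJ-DP4 channel set, and a +/-30 degree dihedral window for the
#' iJ filter (the window width is a package decision and is echoed in all
#' result metadata).
#'
#' @param energy_cutoff Energy window in kJ/mol.
#' @param dedup A [dedup_config()].
#' @param temperature Temperature in K for Boltzmann weighting.
#' @param error_model An [error_model()] or profile name.
#' @param karplus_profile Karplus profile for the iJ filter.
#' @param ij_filter Apply the iJ conformer filter (logical).
#' @param ij_mode `"dihedral_window"` or `"J_match"`.
#' @param ij_tol_deg,ij_tol_J Filter tolerances.
#' @param channels Channels to combine: subsets of `c("H","C","J")`.
#'   `c("H","C")` with `ij_filter = FALSE` is plain DP4; `c("H","C","J")`
#'   without/with the filter is dJ-DP4 / iJ-dJ-DP4.
#' @param j_scale Coupling scaling profile (see [scale_couplings()]).
#' @param curate Apply energy window + dedup inside [run_assignment()]
#'   (default FALSE: ensembles are assumed already curated).
#' @export
assignment_config <- function(energy_cutoff = 12,
                              dedup = dedup_config("MAD", 0.5,
                                                   energy_cutoff = 12),
                              temperature = 298,
                              error_model = "jdp4-2019",
                              karplus_profile = "classical",
                              ij_filter = TRUE,
                              ij_mode = "dihedral_window",
                              ij_tol_deg = 30, ij_tol_J = 2,
                              channels = c("H", "C", "J"),
                              j_scale = "fc-b3lyp",
                              curate = FALSE) {
  if (!all(channels %in% c("H", "C", "J")) || length(channels) == 0L)
    stop("channels must be a non-empty subset of H, C, J")
  if (!inherits(error_model, "error_model"))
    error_model <- error_model(error_model)
  structure(list(energy_cutoff = energy_cutoff, dedup = dedup,
                 temperature = temperature, error_model = error_model,
                 karplus_profile = karplus_profile, ij_filter = ij_filter,
                 ij_mode = ij_mode, ij_tol_deg = ij_tol_deg,
                 ij_tol_J = ij_tol_J, channels = channels,
                 j_scale = j_scale, curate = curate),
            class = "assignment_config")
}

stage <- function(candidate, what, expr) {
  tryCatch(expr, error = function(e)
    stop("candidate '", candidate, "', stage '", what, "': ",
         conditionMessage(e), call. = FALSE))
}

# error-minimizing pairing for signals flagged as a swappable (diastereotopic)
# pair: within each swap group of size 2 in one channel, keep or swap the two
# scaled values, whichever gives the smaller total absolute error.
resolve_swaps <- function(sig, swap_group) {
  if (is.null(swap_group)) return(sig)
  for (g in unique(stats::na.omit(swap_group))) {
    i <- which(!is.na(swap_group) & swap_group == g)
    if (length(i) != 2L) next
    keep <- sum(abs(sig$delta_s[i] - sig$delta_exp[i]))
    swap <- sum(abs(rev(sig$delta_s[i]) - sig$delta_exp[i]))
    if (swap < keep) sig$delta_s[i] <- rev(sig$delta_s[i])
  }
  transform(sig, error = delta_s - delta_exp)
}

candidate_pipeline <- function(cand, e, tbl, cc, exp, ref, cfg) {
  if (cfg$curate) {
    e <- stage(cand, "energy_window",
               apply_energy_window(e, cfg$energy_cutoff))
    e <- stage(cand, "deduplicate", deduplicate(e, cfg$dedup))
  }
  released <- FALSE
  if (cfg$ij_filter) {
    if (is.null(exp$couplings))
      stop("candidate '", cand,
           "': iJ filter requested but no experimental couplings given")
    e <- stage(cand, "ij_filter",
               ij_filter(e, exp$couplings, mode = cfg$ij_mode,
                         karplus_profile = cfg$karplus_profile,
                         tol_deg = cfg$ij_tol_deg, tol_J = cfg$ij_tol_J,
                         couplings_calc = cc))
    released <- isTRUE(attr(e, "filter_released"))
  }
  ids <- conformer_ids(e)
  w <- stage(cand, "boltzmann", boltzmann_weights(e, cfg$temperature))
  tbl_s <- tbl[tbl$conformer_id %in% ids, , drop = FALSE]
  sig_avg <- stage(cand, "average_shieldings", average_shieldings(tbl_s, w))
  du <- stage(cand, "reference", unscaled_shifts(sig_avg, ref))
  signals <- stage(cand, "group_average", group_average(du, exp))
  sc <- stage(cand, "scale", scale_shifts(signals))
  swap_group <- exp$shifts$swap_group
  errors <- list(); diag <- list(); scaling <- list()
  for (el in names(sc)) {
    sg <- resolve_swaps(sc[[el]]$signals,
                        if (is.null(swap_group)) NULL
                        else swap_group[exp$shifts$element == el])
    errors[[el]] <- stats::setNames(sg$error, sg$signal_id)
    diag[[el]] <- prediction_diagnostics(sg$delta_s, sg$delta_exp)
    scaling[[el]] <- list(m = sc[[el]]$m, b = sc[[el]]$b,
                          scaled = sc[[el]]$scaled)
  }
  j_pred <- NULL
  if (!is.null(exp$couplings) && "J" %in% cfg$channels) {
    if (is.null(cc))
      stop("candidate '", cand,
           "': J channel requested but no computed couplings given")
    cp <- exp$couplings
    javg <- vapply(seq_len(nrow(cp)), function(r) {
      rows <- cc[cc$pair_id == cp$pair_id[r], , drop = FALSE]
      pos <- match(ids, rows$conformer_id)
      if (anyNA(pos))
        stop("candidate '", cand, "': computed coupling '", cp$pair_id[r],
             "' missing for conformer(s) ",
             paste(ids[is.na(pos)], collapse = ", "))
      sum(w$weights[ids] * rows$J_hz[pos])
    }, numeric(1))
    jsc <- scale_couplings(javg, cfg$j_scale)
    errors[["J"]] <- stats::setNames(jsc - cp$J_exp_hz, cp$pair_id)
    diag[["J"]] <- prediction_diagnostics(jsc, cp$J_exp_hz)
    j_pred <- stats::setNames(jsc, cp$pair_id)
  }
  list(errors = errors, diagnostics = diag, scaling = scaling,
       weights = w, survivors = ids, filter_released = released,
       delta_s = stats::setNames(
         unlist(lapply(sc, function(x) x$signals$delta_s), use.names = FALSE),
         unlist(lapply(sc, function(x) x$signals$signal_id),
                use.names = FALSE)),
       j_pred = j_pred)
}

#' Run the full assignment pipeline
#'
#' Per candidate stereoisomer: (optional curation) -> optional iJ conformer
#' filter -> Boltzmann weights -> averaged shieldings and couplings ->
#' referencing, equivalence-group averaging and linear scaling -> per-signal
#' errors; then across candidates: Student-t channel probabilities and their
#' combination. Deterministic given inputs and configuration.
#'
#' @param ensembles Named list of [ensemble()]s, one per candidate.
#' @param shieldings Named list of shielding tables (same names).
#' @param exp An [experimental_data()] object shared by all candidates.
#' @param ref A [reference_standard()].
#' @param cfg An [assignment_config()].
#' @param couplings_calc Optional named list (per candidate) of data frames
#'   `conformer_id, pair_id, J_hz` with per-conformer computed couplings.
#' @return Object of class `assignment_result`: candidate ids, per-channel
#'   probabilities (`P_H`, `P_C`, `P_J`), `P_combined`, log-likelihoods,
#'   per-candidate diagnostics and metadata.
#' @export
run_assignment <- function(ensembles, shieldings, exp, ref, cfg,
                           couplings_calc = NULL) {
  stopifnot(inherits(cfg, "assignment_config"),
            inherits(exp, "experimental_data"))
  cands <- names(ensembles)
  if (is.null(cands) || !setequal(cands, names(shieldings)))
    stop("ensembles and shieldings must be named lists over the same ",
         "candidates")
  per <- lapply(cands, function(cand)
    candidate_pipeline(cand, ensembles[[cand]], shieldings[[cand]],
                       couplings_calc[[cand]], exp, ref, cfg))
  names(per) <- cands
  avail <- Reduce(intersect, lapply(per, function(p) names(p$errors)))
  channels <- list()
  for (ch in intersect(cfg$channels, avail)) {
    errs <- lapply(per, function(p) p$errors[[ch]])
    channels[[ch]] <- dp4_channel(errs, cfg$error_model[[ch]])
  }
  if (length(channels) == 0L) stop("no usable data channel")
  combined <- combine_channels(channels, names(channels))
  ff <- unique(vapply(ensembles, `[[`, character(1), "ff_tag"))
  structure(list(
    candidates = cands,
    P_H = channels$H$prob, P_C = channels$C$prob, P_J = channels$J$prob,
    P_combined = combined,
    logliks = lapply(channels, `[[`, "loglik"),
    per_candidate = per,
    metadata = list(ff_tag = paste(ff, collapse = "+"),
                    channels_used = names(channels), config = cfg,
                    filter_released = vapply(per, `[[`, logical(1),
                                             "filter_released"),
                    survivor_counts = vapply(per, function(p)
                      length(p$survivors), integer(1)))),
    class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("<assignment_result> ff=%s channels=%s\n", x$metadata$ff_tag,
              paste(x$metadata$channels_used, collapse = "+")))
  tab <- data.frame(candidate = x$candidates,
                    P_H = fmt_prob(x$P_H, x$candidates),
                    P_C = fmt_prob(x$P_C, x$candidates),
                    P_J = fmt_prob(x$P_J, x$candidates),
                    P_combined = fmt_prob(x$P_combined, x$candidates))
  print(tab, row.names = FALSE)
  invisible(x)
}

# display clamp only: saturated values are kept exact internally
fmt_prob <- function(p, cands) {
  if (is.null(p)) return(rep("-", length(cands)))
  vapply(p[cands], function(v) {
    if (v > 0.999) ">99.9%"
    else if (v < 0.001) "<0.1%"
    else sprintf("%.1f%%", 100 * v)
  }, character(1))
}

#' Average assignment results across force fields (mix-J-DP4)
#'
#' The mix probability of each candidate is the plain arithmetic mean of the
#' per-force-field combined probabilities — no reweighting, no geometric
#' mean — so the mean of valid probability vectors is itself a valid
#' probability vector. Intended for iJ/dJ-DP4 results from independent
#' force-field ensembles (typically AMBER, MM3 and MMFF); two results are
#' accepted with a warning since three independent force fields are the
#' recommended practice.
#'
#' @param results Named list (by force field) of [run_assignment()] results
#'   with identical candidate sets and ordering.
#' @return Object of class `mix_result`: `mix` (averaged combined
#'   probabilities), supplementary per-channel averages, and the per-FF
#'   results.
#' @export
mix_jdp4 <- function(results) {
  if (length(results) < 2L) stop("mix needs >= 2 force-field results")
  if (length(results) == 2L)
    warning("mixing 2 force fields; 3 independent force fields are the ",
            "recommended practice")
  cands <- results[[1L]]$candidates
  for (r in results)
    if (!identical(r$candidates, cands))
      stop("candidate sets differ across force-field results")
  avg <- function(field) {
    vecs <- lapply(results, `[[`, field)
    if (any(vapply(vecs, is.null, logical(1)))) return(NULL)
    Reduce(`+`, lapply(vecs, function(v) v[cands])) / length(vecs)
  }
  structure(list(candidates = cands, mix = avg("P_combined"),
                 mix_H = avg("P_H"), mix_C = avg("P_C"), mix_J = avg("P_J"),
                 per_ff = results),
            class = "mix_result")
}

#' @export
print.mix_result <- function(x, ...) {
  ffs <- names(x$per_ff)
  tab <- data.frame(candidate = x$candidates)
  for (f in ffs)
    tab[[f]] <- fmt_prob(x$per_ff[[f]]$P_combined, x$candidates)
  tab$mix <- fmt_prob(x$mix, x$candidates)
  cat("<mix_result> per-force-field combined probabilities and their mean\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

## ---- classification over ground-truthed fixtures -------------------------

method_config <- function(method, base = assignment_config()) {
  switch(method,
         "dp4" = { base$channels <- c("H", "C"); base$ij_filter <- FALSE },
         "dj-dp4" = { base$channels <- c("H", "C", "J")
                      base$ij_filter <- FALSE },
         "ij-dp4" = { base$channels <- c("H", "C"); base$ij_filter <- TRUE },
         "ij/dj-dp4" = { base$channels <- c("H", "C", "J")
                         base$ij_filter <- TRUE },
         stop("unknown method '", method, "'"))
  base
}

#' Success table over ground-truthed synthetic systems
#'
#' Generates `replicates` independent fixtures, runs each requested method,
#' and reports the fraction of systems whose top-probability candidate is the
#' true one, plus the mean probability assigned to the true candidate.
#'
#' @param spec A [fixture_spec()].
#' @param methods Character vector from `"dp4"`, `"dj-dp4"`, `"ij-dp4"`,
#'   `"ij/dj-dp4"`.
#' @param replicates Number of independent fixtures.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @param base_cfg Base [assignment_config()] modified per method.
#' @return Data frame `method, top_rank_rate, mean_prob_correct, n`.
#' @export
classification_report <- function(spec, methods = c("dp4", "dj-dp4",
                                                    "ij/dj-dp4"),
                                  replicates = 100L, seed = 1L,
                                  base_cfg = assignment_config(
                                    j_scale = "identity")) {
  hits <- matrix(0, nrow = length(methods), ncol = replicates,
                 dimnames = list(methods, NULL))
  pcor <- hits
  for (r in seq_len(replicates)) {
    sp <- spec; sp$seed <- seed + r
    fx <- make_fixture(sp)
    for (m in methods) {
      res <- run_assignment(fx$ensembles, fx$shieldings, fx$exp, fx$ref,
                            method_config(m, base_cfg),
                            couplings_calc = fx$couplings_calc)
      p <- res$P_combined
      hits[m, r] <- names(p)[which.max(p)] == fx$truth$true_candidate
      pcor[m, r] <- p[[fx$truth$true_candidate]]
    }
  }
  data.frame(method = methods,
             top_rank_rate = rowMeans(hits),
             mean_prob_correct = rowMeans(pcor),
             n = replicates, row.names = NULL)
}

## ---- serialization -------------------------------------------------------

#' Write an assignment result to disk
#'
#' Emits `<stem>.json` (full provenance: force-field tag, channel set,
#' configuration, filter decisions, survivor counts), `<stem>.csv` (flat
#' probability table) and `<stem>.txt` (human-readable report).
#'
#' @param x An `assignment_result` or `mix_result`.
#' @param stem Output path stem (no extension).
#' @return The JSON path, invisibly.
#' @export
write_assignment <- function(x, stem) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  if (inherits(x, "mix_result")) {
    tab <- data.frame(candidate = x$candidates)
    for (f in names(x$per_ff))
      tab[[paste0("P_", f)]] <- unname(x$per_ff[[f]]$P_combined[x$candidates])
    tab$P_mix <- unname(x$mix[x$candidates])
    payload <- list(kind = "mix_result", candidates = x$candidates,
                    mix = as.list(x$mix),
                    per_ff = lapply(x$per_ff, result_payload))
  } else {
    tab <- data.frame(candidate = x$candidates,
                      P_H = num_or_na(x$P_H, x$candidates),
                      P_C = num_or_na(x$P_C, x$candidates),
                      P_J = num_or_na(x$P_J, x$candidates),
                      P_combined = unname(x$P_combined[x$candidates]))
    payload <- result_payload(x)
  }
  jsonlite::write_json(payload, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(tab, paste0(stem, ".csv"), row.names = FALSE)
  txt <- utils::capture.output(print(x))
  writeLines(txt, paste0(stem, ".txt"))
  invisible(paste0(stem, ".json"))
}

num_or_na <- function(p, cands) {
  if (is.null(p)) rep(NA_real_, length(cands)) else unname(p[cands])
}

result_payload <- function(x) {
  md <- x$metadata
  cfg <- md$config
  list(kind = "assignment_result", candidates = x$candidates,
       P_H = as.list(x$P_H), P_C = as.list(x$P_C), P_J = as.list(x$P_J),
       P_combined = as.list(x$P_combined),
       diagnostics = lapply(x$per_candidate, function(p)
         lapply(p$diagnostics, function(d)
           list(cmae = d$cmae, max_err = d$max_err))),
       metadata = list(
         ff_tag = md$ff_tag,
         channels_used = md$channels_used,
         filter_released = as.list(md$filter_released),
         survivor_counts = as.list(md$survivor_counts),
         config = if (inherits(cfg, "assignment_config"))
           serialize_config(cfg) else cfg))
}

#' Read back a serialized assignment result
#'
#' Restores the probability vectors and metadata written by
#' [write_assignment()] (sufficient for [mix_jdp4()] and reporting; the
#' per-candidate pipeline intermediates are not round-tripped).
#'
#' @param path Path to the `.json` file.
#' @export
read_assignment <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(j$kind, "mix_result")) {
    per <- lapply(j$per_ff, restore_result)
    return(structure(list(candidates = j$candidates,
                          mix = unlist(j$mix), per_ff = per),
                     class = "mix_result"))
  }
  restore_result(j)
}

restore_result <- function(j) {
  structure(list(candidates = j$candidates,
                 P_H = unlist(j$P_H), P_C = unlist(j$P_C),
                 P_J = unlist(j$P_J),
                 P_combined = unlist(j$P_combined),
                 per_candidate = NULL,
                 metadata = j$metadata),
            class = "assignment_result")
}
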