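# Predicted-observable assembly: Boltzmann-averaged shieldings, TMS
# referencing, linear scaling against experiment, and error diagnostics.

#' TMS reference shieldings
#'
#' Isotropic shieldings of the reference standard computed at the same level
#' of theory as the molecular shieldings. There is no default: the values are
#' level-of-theory dependent and must always be supplied.
#'
#' @param sigma_H,sigma_C Reference shieldings in ppm.
#' @param provenance Non-empty string recording where the values come from
#'   (level of theory, program, ...).
#' @export
reference_standard <- function(sigma_H, sigma_C, provenance) {
  if (!is.finite(sigma_H) || !is.finite(sigma_C))
    stop("reference shieldings must be finite")
  if (missing(provenance) || !nzchar(provenance))
    stop("a provenance string is required for the reference standard")
  structure(list(sigma_H = sigma_H, sigma_C = sigma_C,
                 provenance = provenance),
            class = "reference_standard")
}

#' Read a shielding table
#'
#' CSV with columns `conformer_id, atom_index, element, sigma_ppm`
#' (atom indices 1-based).
#' @param path CSV path.
#' @return Data frame of class `shielding_table`.
#' @export
read_shieldings <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_shielding_table(tab)
}

#' Coerce a data frame to a shielding table
#' @param tab Data frame with columns `conformer_id, atom_index, element,
#'   sigma_ppm`.
#' @export
as_shielding_table <- function(tab) {
  need <- c("conformer_id", "atom_index", "element", "sigma_ppm")
  if (!all(need %in% names(tab)))
    stop("shielding table must have columns ", paste(need, collapse = ", "))
  if (!all(is.finite(tab$sigma_ppm))) stop("non-finite shielding value")
  class(tab) <- c("shielding_table", "data.frame")
  tab
}

#' Read experimental NMR data
#'
#' Shifts CSV: `signal_id, element, atom_indices, delta_exp_ppm` with
#' `atom_indices` semicolon-separated 1-based nuclei treated as one
#' experimental signal (equivalence group). Couplings CSV (optional):
#' `pair_id, h1, h2, dihedral_atoms, J_exp_hz` with `dihedral_atoms` four
#' semicolon-separated indices; an optional logical `filter` column marks
#' filtering-grade couplings (default all).
#'
#' @param shifts_path Path to the shifts CSV.
#' @param couplings_path Optional path to the couplings CSV.
#' @return Object of class `experimental_data`: list with data frames
#'   `shifts` (list-column `atoms`) and `couplings` (list-column `dihedral`).
#' @export
read_experimental <- function(shifts_path, couplings_path = NULL) {
  sh <- utils::read.csv(shifts_path, stringsAsFactors = FALSE)
  need <- c("signal_id", "element", "atom_indices", "delta_exp_ppm")
  if (!all(need %in% names(sh)))
    stop("shifts table must have columns ", paste(need, collapse = ", "))
  sh$atoms <- lapply(strsplit(as.character(sh$atom_indices), ";"), as.integer)
  cp <- NULL
  if (!is.null(couplings_path)) {
    cp <- utils::read.csv(couplings_path, stringsAsFactors = FALSE)
    needc <- c("pair_id", "h1", "h2", "dihedral_atoms", "J_exp_hz")
    if (!all(needc %in% names(cp)))
      stop("couplings table must have columns ",
           paste(needc, collapse = ", "))
    cp$dihedral <- lapply(strsplit(as.character(cp$dihedral_atoms), ";"),
                          as.integer)
    if (any(vapply(cp$dihedral, length, integer(1)) != 4L))
      stop("dihedral_atoms must list exactly 4 indices")
    if (is.null(cp$filter)) cp$filter <- TRUE
    if (any(cp$J_exp_hz < 0)) stop("J_exp must be >= 0")
  }
  experimental_data(sh, cp)
}

#' Construct experimental data from data frames
#' @param shifts Data frame with `signal_id, element, atoms` (list of integer
#'   vectors), `delta_exp_ppm`.
#' @param couplings Optional data frame with `pair_id, h1, h2, dihedral`
#'   (list of 4 integers), `J_exp_hz`, logical `filter`.
#' @export
experimental_data <- function(shifts, couplings = NULL) {
  for (el in unique(shifts$element)) {
    at <- unlist(shifts$atoms[shifts$element == el])
    if (length(at) == 0L) stop("empty equivalence group")
    if (anyDuplicated(at))
      stop("equivalence groups overlap within the ", el, " channel")
  }
  structure(list(shifts = shifts, couplings = couplings),
            class = "experimental_data")
}

#' Boltzmann-average shieldings over an ensemble
#'
#' Per nucleus: `sigma_x = sum_i w_i sigma_i^x`. The weight set and the
#' shielding table must cover exactly the same conformers.
#'
#' @param tbl A shielding table ([as_shielding_table()]).
#' @param w A [boltzmann_weights()] object.
#' @return Data frame with `atom_index, element, sigma_ppm` (one row per
#'   nucleus).
#' @export
average_shieldings <- function(tbl, w) {
  ids_t <- unique(tbl$conformer_id)
  ids_w <- names(w$weights)
  if (!setequal(ids_t, ids_w))
    stop("weights and shielding table cover different conformers: ",
         paste(union(setdiff(ids_t, ids_w), setdiff(ids_w, ids_t)),
               collapse = ", "))
  first <- tbl[tbl$conformer_id == ids_t[1L], ]
  first <- first[order(first$atom_index), ]
  sig <- vapply(first$atom_index, function(a) {
    rows <- tbl[tbl$atom_index == a, ]
    if (!setequal(rows$conformer_id, ids_w))
      stop("nucleus ", a, " missing from some conformers")
    sum(w$weights[rows$conformer_id] * rows$sigma_ppm)
  }, numeric(1))
  data.frame(atom_index = first$atom_index, element = first$element,
             sigma_ppm = sig)
}

#' Unscaled chemical shifts
#'
#' `delta_u = sigma_0 - sigma_x` per nucleus, with the per-element reference
#' shielding from a [reference_standard()].
#'
#' @param sigma_avg Output of [average_shieldings()].
#' @param ref A [reference_standard()].
#' @return Data frame `atom_index, element, delta_u`.
#' @export
unscaled_shifts <- function(sigma_avg, ref) {
  stopifnot(inherits(ref, "reference_standard"))
  bad <- setdiff(unique(sigma_avg$element), c("H", "C"))
  if (length(bad))
    stop("no reference shielding for element(s): ", paste(bad, collapse = ", "))
  s0 <- ifelse(sigma_avg$element == "H", ref$sigma_H, ref$sigma_C)
  data.frame(atom_index = sigma_avg$atom_index,
             element = sigma_avg$element,
             delta_u = s0 - sigma_avg$sigma_ppm)
}

#' Average computed shifts within experimental equivalence groups
#'
#' Experimental signals, not nuclei, are the unit of comparison: equivalent or
#' interchanging protons give one signal, whose predicted value is the
#' arithmetic mean over the group members. Singleton groups pass through.
#'
#' @param delta Data frame `atom_index, element, delta_u` (per nucleus).
#' @param exp An [experimental_data()] object.
#' @return Data frame `signal_id, element, delta_u, delta_exp`, in the order
#'   of the experimental table.
#' @export
group_average <- function(delta, exp) {
  sh <- exp$shifts
  du <- vapply(seq_len(nrow(sh)), function(i) {
    at <- sh$atoms[[i]]
    rows <- match(at, delta$atom_index)
    if (anyNA(rows))
      stop("signal '", sh$signal_id[i], "' references nuclei absent from ",
           "the prediction: ", paste(at[is.na(rows)], collapse = ", "))
    if (any(delta$element[rows] != sh$element[i]))
      stop("signal '", sh$signal_id[i], "' mixes elements")
    mean(delta$delta_u[rows])
  }, numeric(1))
  data.frame(signal_id = sh$signal_id, element = sh$element,
             delta_u = du, delta_exp = sh$delta_exp_ppm)
}

#' Linear scaling of predicted shifts
#'
#' Per element channel, ordinary least squares of `delta_u` (ordinate) against
#' `delta_exp` (abscissa) gives slope `m` and intercept `b`; scaled shifts are
#' `delta_s = (delta_u - b)/m`. Channels with fewer than 3 signals are left
#' unscaled (`delta_s = delta_u`) and flagged; zero variance in `delta_exp`
#' is a degenerate-regression error.
#'
#' @param signals Output of [group_average()].
#' @return List per element channel: `m`, `b`, `scaled` flag and a data frame
#'   `signal_id, delta_u, delta_exp, delta_s, error` (`error = delta_s -
#'   delta_exp`).
#' @export
scale_shifts <- function(signals) {
  out <- list()
  for (el in unique(signals$element)) {
    d <- signals[signals$element == el, ]
    if (nrow(d) < 3L) {
      d$delta_s <- d$delta_u
      out[[el]] <- list(m = NA_real_, b = NA_real_, scaled = FALSE,
                        signals = transform(d, error = delta_s - delta_exp))
      next
    }
    if (stats::sd(d$delta_exp) == 0)
      stop("degenerate regression: zero variance in experimental shifts (",
           el, " channel)")
    fit <- stats::lm(delta_u ~ delta_exp, data = d)
    b <- unname(stats::coef(fit)[1L]); m <- unname(stats::coef(fit)[2L])
    d$delta_s <- (d$delta_u - b) / m
    out[[el]] <- list(m = m, b = b, scaled = TRUE,
                      signals = transform(d, error = delta_s - delta_exp))
  }
  out
}

#' Coupling scaling profiles
#'
#' Fermi-contact-only computed couplings are rescaled linearly,
#' `J_scaled = a * J + c`. `"identity"` leaves values untouched;
#' `"fc-b3lyp"` applies the standard Fermi-contact rescale for B3LYP-quality
#' couplings (a = 0.9117, c = 0). A custom profile is a numeric vector
#' `c(a = , c = )`.
#'
#' @param J Numeric vector of couplings in Hz.
#' @param profile Profile name or `c(a=, c=)` vector.
#' @return Scaled couplings (Hz).
#' @export
scale_couplings <- function(J, profile = "identity") {
  p <- if (is.numeric(profile)) {
    if (!all(c("a", "c") %in% names(profile)))
      stop("custom J-scaling profile must be c(a=, c=)")
    profile
  } else {
    switch(profile,
           identity = c(a = 1, c = 0),
           "fc-b3lyp" = c(a = 0.9117, c = 0),
           stop("unknown J-scaling profile '", profile, "'"))
  }
  p[["a"]] * J + p[["c"]]
}

#' Prediction error diagnostics
#'
#' Per-signal errors `e_j = delta_s_j - delta_exp_j`, their corrected mean
#' absolute error (CMAE, computed on scaled shifts) and maximum absolute
#' error (MaxErr).
#'
#' @param delta_s,delta_exp Matched numeric vectors.
#' @return List `errors`, `cmae`, `max_err`.
#' @export
prediction_diagnostics <- function(delta_s, delta_exp) {
  if (length(delta_s) != length(delta_exp))
    stop("delta_s and delta_exp differ in length")
  e <- delta_s - delta_exp
  list(errors = e, cmae = mean(abs(e)), max_err = max(abs(e)))
}

#' Cross-force-field shielding spread
#'
#' For each nucleus, the difference between the maximum and minimum value
#' across force-field tables (MaxDelta-sigma when fed shieldings,
#' MaxDelta-delta when fed scaled shifts).
#'
#' @param tables Named list (one per force field) of data frames with columns
#'   `atom_index` and a value column (`sigma_ppm` or `delta_s`).
#' @param value Name of the value column (default `"sigma_ppm"`).
#' @return List: `per_nucleus` data frame (`atom_index, spread`) and `summary`
#'   (`min`, `max`, `mean`).
#' @export
max_delta_sigma <- function(tables, value = "sigma_ppm") {
  if (length(tables) < 2L) stop("need >= 2 force-field tables")
  idx <- sort(tables[[1L]]$atom_index)
  vals <- vapply(tables, function(t) {
    rows <- match(idx, t$atom_index)
    if (anyNA(rows)) stop("nucleus missing from a force-field table")
    t[[value]][rows]
  }, numeric(length(idx)))
  vals <- matrix(vals, nrow = length(idx))
  spread <- apply(vals, 1L, max) - apply(vals, 1L, min)
  list(per_nucleus = data.frame(atom_index = idx, spread = spread),
       summary = c(min = min(spread), max = max(spread),
                   mean = mean(spread)))
}
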