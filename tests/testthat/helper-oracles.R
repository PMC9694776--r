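# Independent oracles and small geometry builders used across test files.
# Every oracle here deliberately avoids the package's own code paths.

# random rigid motion
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc - a * d), 2 * (b * d + a * cc),
           2 * (b * cc + a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d - a * b),
           2 * (b * d - a * cc), 2 * (cc * d + a * b),
           a^2 - b^2 - cc^2 + d^2),
         3, 3, byrow = TRUE)
}

rigid_move <- function(coords, R = random_rotation(),
                       t = stats::rnorm(3, sd = 5)) {
  sweep(coords %*% t(R), 2, t, `+`)
}

random_conformer <- function(id, n_atoms = 8, energy = 0,
                             elements = rep("C", n_atoms)) {
  conformer(id, elements, matrix(stats::rnorm(n_atoms * 3, sd = 2),
                                 ncol = 3), energy)
}

# bio3d-based alignment oracle: rmsd and max per-atom deviation after
# least-squares fit (independent superposition code path)
bio3d_rmsd_mad <- function(a, b, idx = seq_along(a$elements)) {
  xa <- as.numeric(t(a$coords)); xb <- as.numeric(t(b$coords))
  xyz_inds <- as.numeric(t(cbind(3 * idx - 2, 3 * idx - 1, 3 * idx)))
  moved <- bio3d::fit.xyz(xa, xb, fixed.inds = xyz_inds,
                          mobile.inds = xyz_inds)
  dev <- sqrt(colSums((matrix(xa[xyz_inds], nrow = 3) -
                       matrix(moved[xyz_inds], nrow = 3))^2))
  list(rmsd = sqrt(mean(dev^2)), mad = max(dev))
}

# independent greedy-dedup oracle: full pairwise distance matrix from the
# bio3d alignment above, then the ascending-energy keep-first scan
oracle_dedup_ids <- function(e, method, threshold) {
  n <- length(e)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- bio3d_rmsd_mad(e$conformers[[i]], e$conformers[[j]])
    dmat[i, j] <- dmat[j, i] <- if (method == "MAD") s$mad else s$rmsd
  }
  ord <- order(rel_energies(e))
  kept <- integer(0)
  for (i in ord)
    if (!length(kept) || all(dmat[i, kept] >= threshold))
      kept <- c(kept, i)
  conformer_ids(e)[kept]
}

# normal-equations least squares (closed form, no lm())
ols_oracle <- function(y, x) {
  n <- length(x)
  m <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  b <- mean(y) - m * mean(x)
  c(m = m, b = b)
}

# direct Student-t density-product probabilities (no log space)
density_product_oracle <- function(errors, sigma, nu, mu = 0) {
  lik <- vapply(errors, function(e)
    prod(stats::dt((e - mu) / sigma, df = nu) / sigma), numeric(1))
  lik / sum(lik)
}

# four points with a prescribed torsion angle, built analytically: chain
# bonds 1.5 A, tetrahedral angles, torsion about the z axis
torsion_points <- function(phi_deg) {
  a <- 70.53 * pi / 180
  p1 <- c(1.5 * sin(a), 0, -1.5 * cos(a))
  p2 <- c(0, 0, 0)
  p3 <- c(0, 0, 1.5)
  phi <- phi_deg * pi / 180
  p4 <- p3 + 1.5 * c(sin(a) * cos(phi), sin(a) * sin(phi), cos(a))
  rbind(p1, p2, p3, p4)
}

tiny_exp_data <- function(n_H = 4, n_C = 4, delta_H = NULL, delta_C = NULL) {
  elem <- c(rep("H", n_H), rep("C", n_C))
  data.frame(signal_id = sprintf("%s%02d", elem, seq_along(elem)),
             element = elem,
             atoms = I(as.list(seq_along(elem))),
             delta_exp_ppm = c(delta_H %||% seq(1, 5, length.out = n_H),
                               delta_C %||% seq(20, 120, length.out = n_C)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_prob_vector <- function(p, tol = 1e-9) {
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(sum(p), 1, tolerance = tol)
}
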