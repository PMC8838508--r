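# Seeded synthetic-trajectory generators: the stand-in for solvated-protein
# MD, with known ground truth for every downstream stage.

#' Build a block-structured target correlation matrix
#'
#' Convenience constructor: starts from the identity and makes the union
#' of the two residue index ranges an equicorrelated cluster at `rho`
#' (every pair within and across the two ranges). The cluster form keeps
#' the matrix positive semi-definite for any `rho >= -1/(k-1)` with `k`
#' cluster sites — a cross-range coupling without within-range coherence
#' would not be a valid correlation matrix for appreciable `rho`.
#' Repeated calls can plant several clusters.
#'
#' @param n number of sites.
#' @param rows,cols integer index vectors of the two coupled ranges.
#' @param rho correlation to plant (may be modestly negative, see above).
#' @param R optional existing matrix to add the cluster to.
#' @return Symmetric `n x n` matrix with unit diagonal.
#' @export
block_correlation <- function(n, rows, cols, rho, R = NULL) {
  if (is.null(R)) R <- diag(n)
  idx <- union(rows, cols)
  R[idx, idx] <- rho
  diag(R) <- 1
  R
}

#' Generate a trajectory with prescribed cross-site correlations
#'
#' Per-frame site displacements are drawn from a zero-mean multivariate
#' normal whose cross-site correlation matrix equals `R`; the same `R`
#' is applied independently to the x, y and z axes, so the expectation
#' of the displacement-vector correlation `<dr_i . dr_j> /
#' sqrt(<dr_i^2><dr_j^2>)` estimated by [compute_dccm()] equals `R_ij`
#' exactly. Displacements are added to a fixed linear-chain reference
#' geometry (3.8 A site spacing, the canonical C-alpha--C-alpha
#' distance). Draws use the symmetric matrix square root of `R`.
#'
#' @param R target correlation matrix: symmetric, unit diagonal,
#'   positive semi-definite.
#' @param sigma per-site displacement scale, Angstrom (scalar or one per
#'   site).
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing, fs (default 5, a typical analysis-snapshot
#'   interval).
#' @param seed integer seed; generation is a pure function of the
#'   arguments.
#' @return A [trajectory()] with `superposed = TRUE` (the ensemble has
#'   no rigid-body component by construction) and pseudo C-alpha atoms
#'   numbered 1..n.
#' @export
generate_correlated_trajectory <- function(R, sigma = 0.5, n_frames = 1000L,
                                           dt = 5, seed = 1L) {
  R <- as.matrix(R)
  n <- nrow(R)
  stopifnot(n == ncol(R), n >= 2L, n_frames >= 2L, all(sigma > 0))
  if (max(abs(R - t(R))) > 1e-10 || max(abs(diag(R) - 1)) > 1e-10) {
    stop("generate_correlated_trajectory: R must be symmetric with unit diagonal")
  }
  es <- eigen((R + t(R)) / 2, symmetric = TRUE)
  tol <- -1e-10 * max(abs(es$values))
  if (min(es$values) < tol) {
    stop(sprintf(
      "generate_correlated_trajectory: R is not positive semi-definite (most negative eigenvalue %.6g)",
      min(es$values)), call. = FALSE)
  }
  S <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))  # symmetric sqrt
  sigma <- rep_len(sigma, n)
  ref <- cbind(3.8 * (seq_len(n) - 1), 0, 0)
  coords <- array(0, c(n_frames, n, 3L))
  set.seed(seed)
  for (a in 1:3) {
    Z <- matrix(rnorm(n_frames * n), n_frames, n)
    D <- (Z %*% S) * rep(sigma, each = n_frames)
    coords[, , a] <- sweep(D, 2, ref[, a], `+`)
  }
  atoms <- data.frame(name = "CA", resname = "ALA", resno = seq_len(n),
                      chain = "A", stringsAsFactors = FALSE)
  trajectory(coords, dt = dt, atoms = atoms, superposed = TRUE)
}

#' Rigid-body motion plus isotropic noise trajectory
#'
#' Frame k places the structure at `R_k x + t_k` plus optional
#' independent Gaussian noise of standard deviation `noise_sd` on every
#' coordinate — the fixture for superposition tests (after an exact
#' Kabsch fit the residual RMSD is 0 for `noise_sd = 0` and approaches
#' `noise_sd * sqrt(3)` for many atoms).
#'
#' @param structure a [structure3d()] (reference geometry).
#' @param rotations list of proper 3 x 3 rotation matrices (det = +1).
#' @param translations list of length-3 vectors, same length as
#'   `rotations`.
#' @param noise_sd per-coordinate Gaussian noise, Angstrom (default 0).
#' @param dt frame spacing, fs.
#' @param seed integer seed.
#' @return A [trajectory()].
#' @export
make_rigid_motion_trajectory <- function(structure, rotations, translations,
                                         noise_sd = 0, dt = 5, seed = 1L) {
  stopifnot(length(rotations) == length(translations), length(rotations) >= 1L)
  x <- if (inherits(structure, "structure3d")) coords3d(structure)
       else as.matrix(structure)
  for (k in seq_along(rotations)) {
    Rk <- rotations[[k]]
    if (max(abs(crossprod(Rk) - diag(3))) > 1e-8 || det(Rk) < 0) {
      stop("make_rigid_motion_trajectory: rotation ", k,
           " is not a proper rotation (orthonormal, det = +1)", call. = FALSE)
    }
  }
  nf <- length(rotations)
  na <- nrow(x)
  coords <- array(0, c(nf, na, 3L))
  set.seed(seed)
  for (k in seq_len(nf)) {
    frame <- tcrossprod(x, rotations[[k]])
    frame <- sweep(frame, 2, as.numeric(translations[[k]]), `+`)
    if (noise_sd > 0) frame <- frame + rnorm(3 * na, sd = noise_sd)
    coords[k, , ] <- frame
  }
  atoms <- if (inherits(structure, "structure3d")) structure else NULL
  trajectory(coords, dt = dt, atoms = atoms)
}

#' Random rotation matrix (uniform over SO(3))
#' @param seed optional integer seed; when NULL the current RNG stream
#'   is used.
#' @return 3 x 3 proper rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
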