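# Simplified harmonic force field for a linear triatomic azide label.
# CHARMM-style energy convention: E = k (x - x0)^2 WITHOUT the 1/2 factor,
# so the Newtonian spring constant of a bond is 2*kb.

#' Harmonic force field for the azide (-N3) label
#'
#' Defaults are the simplified label force field used for long protein
#' simulations: a harmonic N-N bond with equilibrium length 1.14 A and
#' constant 877.413 kcal/mol/A^2, and a harmonic N-N-N bend with
#' equilibrium angle 180 degrees and constant 46.706 kcal/mol/rad^2.
#' The convention is CHARMM-style, `E = k (x - x0)^2` with no 1/2
#' factor, so the constants are used verbatim.
#'
#' @param re equilibrium bond length, Angstrom.
#' @param kb bond force constant, kcal/mol/A^2.
#' @param theta_e equilibrium angle, radians.
#' @param k_theta angle force constant, kcal/mol/rad^2.
#' @return Object of class `label_forcefield`.
#' @export
label_forcefield <- function(re = 1.14, kb = 877.413,
                             theta_e = pi, k_theta = 46.706) {
  if (any(c(re, kb, k_theta) <= 0) || theta_e <= 0 || theta_e > pi) {
    stop("label_forcefield: constants must be positive and 0 < theta_e <= pi")
  }
  out <- list(re = re, kb = kb, theta_e = theta_e, k_theta = k_theta)
  class(out) <- "label_forcefield"
  out
}

#' @export
print.label_forcefield <- function(x, ...) {
  cat(sprintf(
    "label_forcefield: E_bond = %.3f (r - %.3f)^2 kcal/mol, E_angle = %.3f (theta - %.4f)^2 kcal/mol\n",
    x$kb, x$re, x$k_theta, x$theta_e))
  invisible(x)
}

#' Harmonic bond energy and gradient
#'
#' `E(r) = kb (r - re)^2` (kcal/mol), `dE/dr = 2 kb (r - re)`.
#'
#' @param r bond length(s), Angstrom (> 0).
#' @param ff a [label_forcefield()].
#' @return List with `energy` (kcal/mol) and `gradient` (kcal/mol/A),
#'   each the length of `r`.
#' @export
bond_energy <- function(r, ff = label_forcefield()) {
  if (any(r <= 0)) stop("bond_energy: bond length must be positive")
  d <- r - ff$re
  list(energy = ff$kb * d^2, gradient = 2 * ff$kb * d)
}

#' Harmonic angle energy and gradient
#'
#' `E(theta) = k_theta (theta - theta_e)^2` (kcal/mol).
#'
#' @param theta angle(s), radians, in (0, pi].
#' @param ff a [label_forcefield()].
#' @return List with `energy` (kcal/mol) and `gradient` (kcal/mol/rad).
#' @export
angle_energy <- function(theta, ff = label_forcefield()) {
  if (any(theta <= 0 | theta > pi)) {
    stop("angle_energy: angle must lie in (0, pi] radians")
  }
  d <- theta - ff$theta_e
  list(energy = ff$k_theta * d^2, gradient = 2 * ff$k_theta * d)
}

# internal: angle at atom 2 of x (3 x 3 matrix, rows = atoms)
.triatomic_angle <- function(x) {
  u <- x[1, ] - x[2, ]
  v <- x[3, ] - x[2, ]
  ru <- sqrt(sum(u^2)); rv <- sqrt(sum(v^2))
  if (ru < 1e-12 || rv < 1e-12) {
    stop("triatomic geometry error: coincident atoms, angle undefined")
  }
  cth <- sum(u * v) / (ru * rv)
  cth <- max(-1, min(1, cth))
  acos(cth)
}

#' Total energy of the triatomic label
#'
#' Two harmonic bonds (1-2 and 2-3) plus the harmonic 1-2-3 bend.
#'
#' @param x 3 x 3 coordinate matrix (rows = atoms, Angstrom).
#' @param ff a [label_forcefield()].
#' @return Energy in kcal/mol.
#' @export
triatomic_energy <- function(x, ff = label_forcefield()) {
  r12 <- sqrt(sum((x[1, ] - x[2, ])^2))
  r23 <- sqrt(sum((x[3, ] - x[2, ])^2))
  th <- .triatomic_angle(x)
  bond_energy(r12, ff)$energy + bond_energy(r23, ff)$energy +
    angle_energy(th, ff)$energy
}

#' Analytic Cartesian gradient of the triatomic label energy
#'
#' The angle gradient carries a 1/sin(theta) factor that is singular at
#' the linear geometry; because the equilibrium itself is linear
#' (theta_e = pi) the product `(theta - theta_e)/sin(theta)` has a
#' finite limit, which is substituted by its series value when
#' sin(theta) underflows.
#'
#' @param x 3 x 3 coordinate matrix (rows = atoms, Angstrom).
#' @param ff a [label_forcefield()].
#' @return 3 x 3 matrix of dE/dx in kcal/mol/A.
#' @export
triatomic_gradient <- function(x, ff = label_forcefield()) {
  g <- matrix(0, 3, 3)
  u <- x[1, ] - x[2, ]
  v <- x[3, ] - x[2, ]
  ru <- sqrt(sum(u^2)); rv <- sqrt(sum(v^2))
  if (ru < 1e-12 || rv < 1e-12) {
    stop("triatomic geometry error: coincident atoms")
  }
  uh <- u / ru; vh <- v / rv
  # bonds
  db1 <- 2 * ff$kb * (ru - ff$re)
  db3 <- 2 * ff$kb * (rv - ff$re)
  g[1, ] <- g[1, ] + db1 * uh
  g[2, ] <- g[2, ] - db1 * uh - db3 * vh
  g[3, ] <- g[3, ] + db3 * vh
  # angle
  cth <- max(-1, min(1, sum(uh * vh)))
  th <- acos(cth)
  sth <- sqrt(max(0, 1 - cth^2))
  if (sth < 1e-8) {
    # near-linear: (theta - theta_e)/sin(theta) -> -(1 + delta^2/6) for
    # theta_e = pi, delta = pi - theta
    delta <- pi - th
    f <- if (abs(ff$theta_e - pi) < 1e-12) {
      2 * ff$k_theta * (1 + delta^2 / 6)
    } else {
      -2 * ff$k_theta * (th - ff$theta_e) / max(sth, 1e-8)
    }
  } else {
    f <- -2 * ff$k_theta * (th - ff$theta_e) / sth
  }
  d1 <- f * (vh - cth * uh) / ru
  d3 <- f * (uh - cth * vh) / rv
  g[1, ] <- g[1, ] + d1
  g[3, ] <- g[3, ] + d3
  g[2, ] <- g[2, ] - d1 - d3
  g
}

#' Normal modes of the collinear triatomic label
#'
#' Diagonalizes the mass-weighted Hessian of the harmonic label force
#' field at a collinear equilibrium geometry (spacing `re`). The Hessian
#' is assembled analytically: each bond contributes the outer-product
#' block `2 kb r_hat r_hat^T` (the effective spring constant is `2 kb`
#' under the no-1/2 convention) and the linear bend contributes
#' `2 k_theta g_i g_j P` where `P` projects perpendicular to the
#' molecular axis and `g = (1/r12, -(1/r12 + 1/r23), 1/r23)`.
#' A linear triatomic has exactly 5 zero modes (3 translations, 2
#' rotations); the remaining 4 are the two stretches and the doubly
#' degenerate bend.
#'
#' @param masses numeric(3), amu.
#' @param ff a [label_forcefield()].
#' @param geometry optional 3 x 3 coordinate matrix; defaults to the
#'   collinear equilibrium along z. A non-equilibrium input triggers a
#'   warning but the Hessian is still evaluated at that geometry's axis.
#' @return Object of class `normal_modes`: `frequencies` (cm^-1,
#'   ascending, zero modes reported as 0), `modes` (columns,
#'   mass-weighted orthonormal eigenvectors, same order), `zero_modes`
#'   (count), `eigenvalues` (kcal/mol/A^2/amu).
#' @export
normal_modes <- function(masses, ff = label_forcefield(), geometry = NULL) {
  stopifnot(length(masses) == 3, all(masses > 0))
  if (is.null(geometry)) {
    geometry <- rbind(c(0, 0, -ff$re), c(0, 0, 0), c(0, 0, ff$re))
  }
  u <- geometry[1, ] - geometry[2, ]
  v <- geometry[3, ] - geometry[2, ]
  r12 <- sqrt(sum(u^2)); r23 <- sqrt(sum(v^2))
  th <- .triatomic_angle(geometry)
  if (abs(r12 - ff$re) > 1e-6 * ff$re || abs(r23 - ff$re) > 1e-6 * ff$re ||
      abs(th - ff$theta_e) > 1e-6) {
    warning("normal_modes: input geometry is not the force-field equilibrium; ",
            "Hessian evaluated at the equilibrium expansion about this axis",
            call. = FALSE)
  }
  uh <- u / r12
  vh <- v / r23
  H <- matrix(0, 9, 9)
  add_bond <- function(H, a, b, rhat, k) {
    blk <- 2 * k * tcrossprod(rhat)
    ia <- (3 * a - 2):(3 * a); ib <- (3 * b - 2):(3 * b)
    H[ia, ia] <- H[ia, ia] + blk
    H[ib, ib] <- H[ib, ib] + blk
    H[ia, ib] <- H[ia, ib] - blk
    H[ib, ia] <- H[ib, ia] - blk
    H
  }
  H <- add_bond(H, 1L, 2L, uh, ff$kb)
  H <- add_bond(H, 2L, 3L, vh, ff$kb)
  # linear bend: axis from atom 1 to atom 3
  n <- geometry[3, ] - geometry[1, ]
  n <- n / sqrt(sum(n^2))
  P <- diag(3) - tcrossprod(n)
  gvec <- c(1 / r12, -(1 / r12 + 1 / r23), 1 / r23)
  for (i in 1:3) for (j in 1:3) {
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] + 2 * ff$k_theta * gvec[i] * gvec[j] * P
  }
  minv <- rep(1 / sqrt(masses), each = 3)
  Hmw <- H * tcrossprod(minv)
  es <- eigen(Hmw, symmetric = TRUE)
  lambda <- rev(es$values)          # ascending
  modes <- es$vectors[, rev(seq_len(9)), drop = FALSE]
  tol <- max(abs(lambda)) * 1e-10
  zero <- abs(lambda) < tol
  lambda[zero] <- 0
  freqs <- ifelse(zero, 0, eigenvalue_to_wavenumber(pmax(lambda, 0)))
  out <- list(frequencies = freqs, modes = modes,
              zero_modes = sum(zero), eigenvalues = lambda)
  class(out) <- "normal_modes"
  out
}

#' @export
print.normal_modes <- function(x, ...) {
  nz <- x$frequencies[x$frequencies > 0]
  cat(sprintf("normal_modes: %d zero modes; vibrational frequencies (cm^-1): %s\n",
              x$zero_modes, paste(sprintf("%.2f", nz), collapse = ", ")))
  invisible(x)
}
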