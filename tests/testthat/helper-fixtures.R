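# Shared fixtures and independent oracles, built in code at test time.

# hand-formatted fixed-column PDB ATOM line (wwPDB 3.3)
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element = substr(name, 1, 1), altloc = " ") {
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %-4s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, altloc, resname, chain, resno, x, y, z, 1, 0, element)
}

# n-residue poly-alanine C-alpha structure on a gentle helix
make_ca_structure <- function(n, spacing = 3.8) {
  t <- seq_len(n)
  structure3d(data.frame(
    name = "CA", resname = "ALA", resno = t, chain = "A",
    x = 2.3 * cos(t / 1.75), y = 2.3 * sin(t / 1.75), z = 1.5 * t,
    stringsAsFactors = FALSE))
}

# rotation matrix from z-y-z Euler angles (independent of the package's
# quaternion-based random_rotation)
euler_rotation <- function(a, b, g) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(g)
}

# brute-force minimal RMSD over rotations: coarse Euler grid followed by
# Nelder-Mead refinement; never touches the SVD path.
brute_force_min_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  obj <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((tcrossprod(P, R) - Q)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 13L)[-13L]
  bgrid <- seq(0, pi, length.out = 7L)
  best <- NULL; bestv <- Inf
  for (a in grid) for (b in bgrid) for (g in grid) {
    v <- obj(c(a, b, g))
    if (v < bestv) { bestv <- v; best <- c(a, b, g) }
  }
  for (i in 1:3) {
    o <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 5000))
    best <- o$par
  }
  o$value
}

# naive double-loop DCCM (the independent oracle for compute_dccm)
naive_dccm <- function(coords, selection = NULL) {
  nf <- dim(coords)[1]
  if (is.null(selection)) selection <- seq_len(dim(coords)[2])
  ns <- length(selection)
  disp <- array(0, c(nf, ns, 3))
  for (s in seq_len(ns)) {
    for (a in 1:3) {
      x <- coords[, selection[s], a]
      disp[, s, a] <- x - mean(x)
    }
  }
  C <- matrix(0, ns, ns)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    num <- mean(rowSums(disp[, i, , drop = FALSE] * disp[, j, , drop = FALSE]))
    di <- mean(rowSums(disp[, i, , drop = FALSE]^2))
    dj <- mean(rowSums(disp[, j, , drop = FALSE]^2))
    C[i, j] <- num / sqrt(di * dj)
  }
  C
}

# direct O(N^2) dipole autocorrelation with biased normalization
naive_dipole_acf <- function(values, n_lags) {
  n <- nrow(values)
  x <- sweep(values, 2, colMeans(values))
  vapply(seq_len(n_lags) - 1L, function(tau) {
    idx <- seq_len(n - tau)
    sum(rowSums(x[idx, , drop = FALSE] * x[idx + tau, , drop = FALSE])) / n
  }, numeric(1))
}
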