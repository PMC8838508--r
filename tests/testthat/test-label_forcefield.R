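test_that("bond and angle terms follow the no-half CHARMM convention verbatim", {
  ff <- label_forcefield()
  expect_equal(ff$re, 1.14)
  expect_equal(ff$kb, 877.413)
  expect_equal(ff$theta_e, pi)
  expect_equal(ff$k_theta, 46.706)

  expect_equal(bond_energy(1.14, ff)$energy, 0)
  expect_equal(bond_energy(1.24, ff)$energy, 877.413 * 0.1^2, tolerance = 1e-12)
  expect_equal(bond_energy(1.14, ff)$gradient, 0)
  expect_error(bond_energy(-0.1, ff), "positive")

  expect_equal(angle_energy(pi, ff)$energy, 0)
  expect_equal(angle_energy(170 * pi / 180, ff)$energy,
               46.706 * (10 * pi / 180)^2, tolerance = 1e-12)
  expect_equal(angle_energy(pi, ff)$gradient, 0)
  expect_error(angle_energy(0, ff), "angle")
})

test_that("the bond energy is the line integral of its gradient", {
  ff <- label_forcefield()
  # trapezoid integration of dE/dr from re to 1.24 recovers E(1.24)
  r <- seq(ff$re, 1.24, length.out = 2001)
  g <- bond_energy(r, ff)$gradient
  e_int <- sum((g[-1] + g[-length(g)]) / 2) * diff(r[1:2])
  expect_equal(e_int, bond_energy(1.24, ff)$energy, tolerance = 1e-8)
})

test_that("analytic Cartesian gradients match central finite differences", {
  ff <- label_forcefield()
  set.seed(7)
  h <- 1e-5
  for (case in 1:12) {
    # bent, stretched geometries around equilibrium
    x <- rbind(c(0, 0, -ff$re), c(0, 0, 0), c(0, 0, ff$re)) +
      matrix(rnorm(9, sd = 0.08), 3, 3)
    g <- triatomic_gradient(x, ff)
    for (i in 1:3) for (a in 1:3) {
      xp <- x; xp[i, a] <- xp[i, a] + h
      xm <- x; xm[i, a] <- xm[i, a] - h
      fd <- (triatomic_energy(xp, ff) - triatomic_energy(xm, ff)) / (2 * h)
      expect_equal(g[i, a], fd, tolerance = 1e-6 * max(1, abs(fd)))
    }
  }
})

test_that("forces are translation- and rotation-invariant (zero net force and torque)", {
  ff <- label_forcefield()
  set.seed(9)
  for (case in 1:8) {
    x <- rbind(c(0, 0, -ff$re), c(0, 0, 0), c(0, 0, ff$re)) +
      matrix(rnorm(9, sd = 0.1), 3, 3)
    g <- triatomic_gradient(x, ff)
    expect_equal(colSums(g), c(0, 0, 0), tolerance = 1e-10)
    torque <- colSums(t(vapply(1:3, function(i) {
      c(x[i, 2] * g[i, 3] - x[i, 3] * g[i, 2],
        x[i, 3] * g[i, 1] - x[i, 1] * g[i, 3],
        x[i, 1] * g[i, 2] - x[i, 2] * g[i, 1])
    }, numeric(3))))
    expect_equal(torque, c(0, 0, 0), tolerance = 1e-9)
  }
})

test_that("the gradient is finite and vanishing at the exactly linear equilibrium", {
  ff <- label_forcefield()
  x <- rbind(c(0, 0, -ff$re), c(0, 0, 0), c(0, 0, ff$re))
  g <- triatomic_gradient(x, ff)
  expect_true(all(is.finite(g)))
  expect_equal(max(abs(g)), 0, tolerance = 1e-10)
})

test_that("equal-mass normal modes give the analytic chain spectrum", {
  m <- rep(14.003074, 3)
  nm <- normal_modes(m)
  expect_equal(nm$zero_modes, 5L)
  vib <- nm$frequencies[nm$frequencies > 0]
  expect_length(vib, 4L)
  # stretch eigenvalues of the equal-mass chain are {K/m, 3K/m}:
  # frequency ratio asym/sym = sqrt(3)
  stretches <- sort(vib, decreasing = TRUE)[1:2]
  expect_equal(stretches[1] / stretches[2], sqrt(3), tolerance = 1e-8)
  # absolute asymmetric-stretch value from the closed form
  K <- 2 * 877.413
  omega <- sqrt(3 * K / 14.003074 * pd_constants$kcal_per_mol_to_akma)
  expect_equal(max(vib), omega / (2 * pi * pd_constants$c_cm_fs),
               tolerance = 1e-10)
  # bend is doubly degenerate
  expect_equal(vib[1], vib[2], tolerance = 1e-8)
})

test_that("normal-mode frequencies are invariant under rigid rotation of the geometry", {
  m <- c(14.003074, 14.003074, 15.9949)
  ff <- label_forcefield()
  geo <- rbind(c(0, 0, -ff$re), c(0, 0, 0), c(0, 0, ff$re))
  nm0 <- normal_modes(m, ff, geo)
  Rr <- random_rotation(seed = 21)
  nm1 <- normal_modes(m, ff, tcrossprod(geo, Rr))
  expect_equal(nm1$frequencies, nm0$frequencies, tolerance = 1e-8)
  expect_equal(nm1$zero_modes, 5L)
})

test_that("eigenvectors are orthonormal in the mass-weighted metric", {
  nm <- normal_modes(c(14.003074, 12.011, 15.9949))
  G <- crossprod(nm$modes)
  expect_equal(G, diag(9), tolerance = 1e-10)
})

test_that("a non-equilibrium geometry is flagged but still evaluated", {
  ff <- label_forcefield()
  geo <- rbind(c(0, 0, -1.3), c(0, 0, 0), c(0, 0, 1.3))
  expect_warning(nm <- normal_modes(rep(14, 3), ff, geo), "not the force-field equilibrium")
  expect_true(all(is.finite(nm$frequencies)))
})
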