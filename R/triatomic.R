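# Langevin dynamics of the harmonic triatomic label (BAOAB splitting of
# velocity Verlet). With friction = 0 the O-step is the identity and the
# integrator reduces to plain (symplectic) velocity Verlet.

#' Simulate the triatomic azide label with Langevin dynamics
#'
#' Propagates the three label atoms under the harmonic
#' [label_forcefield()] using the BAOAB splitting: half kick, half
#' drift, Ornstein-Uhlenbeck velocity refresh, half drift, half kick.
#' The dipole moment per saved frame is `sum_i q_i r_i`. Initial
#' velocities are drawn from the Maxwell-Boltzmann distribution at
#' `temperature` (zero when `temperature = 0`).
#'
#' Label partial charges have no published values for the simplified
#' force field; the defaults `(0.2, -0.4, 0.2)` e are arbitrary,
#' charge-neutral test values that make the asymmetric stretch
#' IR-active. Default friction 10 ps^-1 is a common solvent-like
#' Langevin thermostat rate.
#'
#' @param n_steps number of integration steps.
#' @param timestep dt in fs; must be below one tenth of the fastest
#'   normal-mode period or a configuration error is raised.
#' @param temperature K.
#' @param friction Langevin friction, ps^-1 (0 = NVE velocity Verlet).
#' @param masses atom masses, amu (default three nitrogens).
#' @param charges partial charges, e; their sum is the net label charge.
#' @param ff a [label_forcefield()].
#' @param seed integer seed (all randomness flows from it).
#' @param save_every save state every this many steps.
#' @param x0 optional 3 x 3 initial coordinates (default: collinear
#'   equilibrium along z).
#' @param v0 optional 3 x 3 initial velocities, A/fs (overrides the
#'   Maxwell-Boltzmann draw).
#' @param engine `"cpp"` (default) or `"R"` (reference implementation,
#'   identical algorithm, used for cross-checking).
#' @return List of class `triatomic_sim` with `trajectory` (a
#'   [trajectory()]), `dipole` (a [dipole_series()], e*A), and
#'   `energies` (data frame: `time` fs, `kinetic`, `potential`,
#'   `total` kcal/mol).
#' @export
simulate_triatomic <- function(n_steps, timestep = 0.25, temperature = 300,
                               friction = 10, masses = rep(14.003074, 3),
                               charges = c(0.2, -0.4, 0.2),
                               ff = label_forcefield(), seed = 1L,
                               save_every = 1L, x0 = NULL, v0 = NULL,
                               engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  stopifnot(n_steps >= 1L, timestep > 0, temperature >= 0, friction >= 0,
            length(masses) == 3, all(masses > 0), length(charges) == 3)
  nm <- normal_modes(masses, ff)
  numax <- max(nm$frequencies)
  period <- 1 / (numax * pd_constants$c_cm_fs)   # fs
  if (timestep > period / 10) {
    stop(sprintf(
      "simulate_triatomic: timestep %.4g fs exceeds the stability bound %.4g fs (fastest mode period %.4g fs / 10)",
      timestep, period / 10, period), call. = FALSE)
  }
  if (is.null(x0)) {
    x0 <- rbind(c(0, 0, -ff$re), c(0, 0, 0), c(0, 0, ff$re))
  }
  x0 <- as.matrix(x0)
  set.seed(seed)
  if (is.null(v0)) {
    if (temperature > 0) {
      vsd <- sqrt(pd_constants$kB * temperature *
                    pd_constants$kcal_per_mol_to_akma / masses)
      v0 <- matrix(rnorm(9), 3, 3) * vsd
    } else {
      v0 <- matrix(0, 3, 3)
    }
  }
  gamma_fs <- friction / 1000                    # ps^-1 -> fs^-1
  xflat <- as.numeric(t(x0))                     # atom-major x1 y1 z1 x2 ...
  vflat <- as.numeric(t(as.matrix(v0)))
  res <- if (engine == "cpp") {
    .triatomic_baoab_cpp(xflat, vflat, masses, charges,
                         ff$re, ff$kb, ff$theta_e, ff$k_theta,
                         timestep, gamma_fs, temperature,
                         as.integer(n_steps), as.integer(save_every))
  } else {
    .triatomic_baoab_r(xflat, vflat, masses, charges, ff,
                       timestep, gamma_fs, temperature,
                       as.integer(n_steps), as.integer(save_every))
  }
  n_save <- nrow(res$coords)
  coords <- array(0, c(n_save, 3L, 3L))
  for (at in 1:3) coords[, at, ] <- res$coords[, (3 * at - 2):(3 * at)]
  atoms <- data.frame(name = c("N1", "N2", "N3"), resname = "AZI",
                      resno = c(1L, 1L, 1L), chain = "X",
                      stringsAsFactors = FALSE)
  dt_save <- timestep * save_every
  out <- list(
    trajectory = trajectory(coords, dt = dt_save, atoms = atoms),
    dipole = dipole_series(res$dipole, dt = dt_save,
                           label = "triatomic label (e*A)"),
    energies = data.frame(time = seq_len(n_save) * dt_save,
                          kinetic = res$kinetic, potential = res$potential,
                          total = res$kinetic + res$potential)
  )
  class(out) <- "triatomic_sim"
  out
}

#' @export
print.triatomic_sim <- function(x, ...) {
  cat(sprintf(
    "triatomic_sim: %d saved frames, dt = %g fs, <KE> = %.4g kcal/mol\n",
    n_frames(x$trajectory), x$trajectory$dt, mean(x$energies$kinetic)))
  invisible(x)
}

# Pure-R BAOAB reference, step-for-step identical to the C++ engine
# (same RNG draw order), used in tests as the cross-check oracle.
.triatomic_baoab_r <- function(x, v, masses, charges, ff, dt, gamma,
                               temperature, n_steps, save_every) {
  conv <- pd_constants$kcal_per_mol_to_akma
  kBT <- pd_constants$kB * temperature * conv
  m <- rep(masses, each = 3)
  c1 <- exp(-gamma * dt)
  sig <- if (gamma > 0) sqrt(kBT * (1 - c1^2) / m) else rep(0, 9)
  grad_of <- function(xf) {
    g <- triatomic_gradient(matrix(xf, 3, 3, byrow = TRUE), ff)
    as.numeric(t(g))
  }
  ener_of <- function(xf) triatomic_energy(matrix(xf, 3, 3, byrow = TRUE), ff)
  n_save <- n_steps %/% save_every
  coords <- matrix(0, n_save, 9)
  dipole <- matrix(0, n_save, 3)
  kin <- pot <- numeric(n_save)
  g <- grad_of(x)
  isave <- 0L
  for (step in seq_len(n_steps)) {
    v <- v - 0.5 * dt * g * conv / m
    x <- x + 0.5 * dt * v
    if (gamma > 0) v <- c1 * v + sig * rnorm(9)
    x <- x + 0.5 * dt * v
    g <- grad_of(x)
    v <- v - 0.5 * dt * g * conv / m
    if (step %% save_every == 0L) {
      isave <- isave + 1L
      kin[isave] <- sum(0.5 * m * v^2) / conv
      pot[isave] <- ener_of(x)
      xm <- matrix(x, 3, 3, byrow = TRUE)
      dipole[isave, ] <- colSums(charges * xm)
      coords[isave, ] <- x
    }
  }
  list(coords = coords, dipole = dipole, kinetic = kin, potential = pot)
}
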