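# Internal unit system: Angstrom, femtosecond, amu, kcal/mol.
# Frequencies leave the package only in cm^-1; the conversion lives here and
# nowhere else.

#' Physical constants used by protdyn
#'
#' The package works internally in Angstrom / femtosecond / amu / kcal/mol.
#' `kB` is Boltzmann's constant in kcal/mol/K; `kcal_per_mol_to_akma`
#' converts an energy in kcal/mol to amu A^2/fs^2 (so a force in
#' kcal/mol/A times this factor divided by a mass in amu is an
#' acceleration in A/fs^2); `c_cm_fs` is the speed of light in cm/fs;
#' `hc_over_kB` is the second radiation constant h*c/kB in cm K, used by
#' the quantum correction factor.
#'
#' @format A named list of scalars.
#' @export
pd_constants <- list(
  kB = 0.0019872041,                 # kcal/mol/K
  kcal_per_mol_to_akma = 4.184e-04,  # kcal/mol -> amu A^2 / fs^2
  c_cm_fs = 2.99792458e-05,          # speed of light, cm/fs
  hc_over_kB = 1.43877687750393      # h c / kB, cm K
)

# angular frequency (rad/fs) -> wavenumber (cm^-1)
omega_to_wavenumber <- function(omega) {
  omega / (2 * pi * pd_constants$c_cm_fs)
}

# mass-weighted Hessian eigenvalue (kcal/mol/A^2/amu) -> wavenumber (cm^-1)
eigenvalue_to_wavenumber <- function(lambda) {
  omega_to_wavenumber(sqrt(lambda * pd_constants$kcal_per_mol_to_akma))
}
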