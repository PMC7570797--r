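#' Physical constants used throughout the package
#'
#' Returns the CODATA-2018 constants the photophysics formulas are assembled
#' from, together with a handful of derived conversion factors.  All derived
#' factors are computed from the primary constants at call time so that the
#' round-trip identities hold to machine precision.
#'
#' @return A named list with elements
#'   \describe{
#'     \item{alpha}{fine-structure constant (dimensionless)}
#'     \item{a0_m}{Bohr radius in m}
#'     \item{t0_s}{atomic unit of time in s}
#'     \item{eps0}{vacuum permittivity in F/m}
#'     \item{hbar}{reduced Planck constant in J s}
#'     \item{c_ms}{speed of light in m/s}
#'     \item{kB_J}{Boltzmann constant in J/K}
#'     \item{kB_kcal}{Boltzmann constant in kcal mol^-1 K^-1}
#'     \item{hartree_eV}{1 hartree in eV}
#'     \item{hc_eVnm}{the product E[eV] * lambda[nm] for a photon}
#'     \item{au_dipole_Cm}{1 atomic unit of dipole moment in C m}
#'     \item{au_dipole_debye}{1 atomic unit of dipole moment in debye}
#'     \item{e_C}{elementary charge in C}
#'     \item{beta_au_esu}{1 atomic unit of first hyperpolarizability in esu}
#'     \item{gm_per_au_area_time}{a0^4 * t0 expressed in Goeppert-Mayer
#'       units (1 GM = 1e-50 cm^4 s / photon)}
#'   }
#' @export
#' @examples
#' k <- photophysics_constants()
#' k$hartree_eV
photophysics_constants <- function() {
  alpha <- 7.2973525693e-3
  a0_m  <- 5.29177210903e-11
  t0_s  <- 2.4188843265857e-17
  eps0  <- 8.8541878128e-12
  hbar  <- 1.054571817e-34
  c_ms  <- 299792458
  e_C   <- 1.602176634e-19
  kB_J  <- 1.380649e-23
  NA_mol <- 6.02214076e23

  hartree_J  <- 4.3597447222071e-18
  hartree_eV <- hartree_J / e_C
  # E[eV] * lambda[nm] for a photon: h c / e * 1e9
  hc_eVnm <- (2 * pi * hbar) * c_ms / e_C * 1e9

  au_dipole_Cm    <- e_C * a0_m
  au_dipole_debye <- au_dipole_Cm / 3.33564095198152e-30

  # 1 au of beta = e^3 a0^3 / E_h^2, evaluated in Gaussian cgs (esu)
  e_esu      <- 4.80320471257e-10   # statC
  a0_cm      <- a0_m * 100
  hartree_erg <- hartree_J * 1e7
  beta_au_esu <- e_esu^3 * a0_cm^3 / hartree_erg^2

  # a0^4 t0 in cm^4 s, expressed per GM (1 GM = 1e-50 cm^4 s)
  gm_per_au_area_time <- a0_cm^4 * t0_s * 1e50

  kB_kcal <- kB_J * NA_mol / 4184   # kcal mol^-1 K^-1

  list(alpha = alpha, a0_m = a0_m, t0_s = t0_s, eps0 = eps0, hbar = hbar,
       c_ms = c_ms, e_C = e_C, kB_J = kB_J, kB_kcal = kB_kcal,
       hartree_eV = hartree_eV, hc_eVnm = hc_eVnm,
       au_dipole_Cm = au_dipole_Cm, au_dipole_debye = au_dipole_debye,
       beta_au_esu = beta_au_esu,
       gm_per_au_area_time = gm_per_au_area_time)
}

#' Convert photon/transition energies between common units
#'
#' Bijective conversion between the units quantum-chemistry outputs and
#' spectroscopy plots use.  `"hartree"` and `"au_omega"` (angular frequency
#' in atomic units, where hbar = 1) are numerically identical and both
#' accepted.  The eV/nm conversion uses E\[eV\] * lambda\[nm\] = hc.
#'
#' @param value numeric vector of energies (or wavelengths for `from = "nm"`).
#' @param from,to one of `"eV"`, `"nm"`, `"hartree"`, `"au_omega"`.
#' @return numeric vector in the target unit.
#' @export
#' @examples
#' convert_energy(1239.84, "nm", "eV")   # ~1 eV
#' convert_energy(1, "hartree", "eV")    # 27.2114
convert_energy <- function(value, from, to) {
  units <- c("eV", "nm", "hartree", "au_omega")
  from <- match.arg(from, units)
  to   <- match.arg(to, units)
  if (!is.numeric(value)) stop("`value` must be numeric")
  k <- photophysics_constants()
  if (any(is.finite(value) & value <= 0)) {
    stop("energies/wavelengths must be positive")
  }
  to_ev <- switch(from,
    eV       = value,
    nm       = k$hc_eVnm / value,
    hartree  = value * k$hartree_eV,
    au_omega = value * k$hartree_eV)
  switch(to,
    eV       = to_ev,
    nm       = k$hc_eVnm / to_ev,
    hartree  = to_ev / k$hartree_eV,
    au_omega = to_ev / k$hartree_eV)
}
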