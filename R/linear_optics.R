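#' Oscillator strength of a transition
#'
#' f = (2/3) * omega * |mu|^2, everything in atomic units.
#'
#' @param omega_au excitation (angular) frequency in atomic units (> 0).
#' @param tdm transition dipole moment: a length-3 vector or a single
#'   magnitude, atomic units.
#' @return the dimensionless oscillator strength (>= 0).
#' @export
#' @examples
#' oscillator_strength(0.15, c(3, 0, 0))  # (2/3)*0.15*9 = 0.9
oscillator_strength <- function(omega_au, tdm) {
  if (!is.finite(omega_au) || omega_au <= 0)
    stop("excitation energy must be > 0")
  mu2 <- if (length(tdm) == 3) sum(tdm^2) else tdm^2
  (2 / 3) * omega_au * mu2
}

#' Transition-dipole orientation and photoselection weights
#'
#' For each frame, the angle between the requested state's transition
#' dipole moment and the membrane normal (arccos of the normalized dot
#' product, reported unfolded in \[0, 180\] degrees so that flip-flopped
#' orientations remain distinguishable) together with the photoselection
#' weight cos^2(angle) for excitation polarized along the normal.  By the
#' head-tail symmetry of a rod-like probe, angles theta and 180 - theta
#' denote the same physical orientation and carry the same weight.
#'
#' @param frames list of `frame_record` objects.
#' @param state_index which excited state (default 1 = S1).
#' @return data.frame with columns `frame_id`, `state_index`, `angle_deg`,
#'   `wavelength_nm`, `weight`, `flagged` (TRUE for zero-length dipoles,
#'   whose angle is undefined and reported as NA).
#' @export
tdm_orientation <- function(frames, state_index = 1) {
  rows <- lapply(frames, function(fr) {
    s <- state_by_index(fr, state_index)
    if (is.null(s))
      stop("state ", state_index, " missing in frame ", fr$frame_id)
    mu <- s$tdm
    nrm <- sqrt(sum(mu^2))
    if (nrm == 0) {
      data.frame(frame_id = fr$frame_id, state_index = state_index,
                 angle_deg = NA_real_,
                 wavelength_nm = convert_energy(s$excitation_energy,
                                                "eV", "nm"),
                 weight = NA_real_, flagged = TRUE)
    } else {
      ct <- sum(mu * fr$membrane_normal) / nrm
      ct <- min(1, max(-1, ct))
      data.frame(frame_id = fr$frame_id, state_index = state_index,
                 angle_deg = acos(ct) * 180 / pi,
                 wavelength_nm = convert_energy(s$excitation_energy,
                                                "eV", "nm"),
                 weight = ct^2, flagged = FALSE)
    }
  })
  do.call(rbind, rows)
}

# unit-area lineshape in energy space; gamma_ev is the full width at half
# maximum for both shapes
lineshape_density <- function(de, gamma_ev, lineshape) {
  switch(lineshape,
    lorentzian = {
      hw <- gamma_ev / 2
      (hw / pi) / (de^2 + hw^2)
    },
    gaussian = {
      sd <- gamma_ev / (2 * sqrt(2 * log(2)))
      stats::dnorm(de, 0, sd)
    },
    stop("unknown lineshape: ", lineshape))
}

#' Ensemble-broadened one-photon absorption spectrum
#'
#' Each (frame, state) contributes a unit-area lineshape in energy space
#' centered at its excitation energy and scaled by its oscillator strength
#' (times the photoselection weight cos^2 theta if requested).  The
#' ensemble average is mapped onto the wavelength grid with the Jacobian
#' |dE/dlambda| = hc / lambda^2, so the wavelength-integral of the
#' unweighted total equals the ensemble-mean total oscillator strength on
#' a sufficiently wide grid.
#'
#' @param frames list of `frame_record` objects.
#' @param states integer vector of state indices to include (default: all
#'   present in the first frame).
#' @param grid increasing wavelength grid in nm.
#' @param gamma_ev broadening FWHM in eV (default 0.1).
#' @param lineshape `"lorentzian"` (default) or `"gaussian"`.
#' @param weighting `"none"` or `"photoselection"`.
#' @return object of class `spectrum`: data.frame with `wavelength_nm`,
#'   `total` and one `s<k>` column per state; broadening parameters kept
#'   as attributes.
#' @export
broadened_spectrum <- function(frames, states = NULL, grid,
                               gamma_ev = 0.1,
                               lineshape = c("lorentzian", "gaussian"),
                               weighting = c("none", "photoselection")) {
  lineshape <- match.arg(lineshape)
  weighting <- match.arg(weighting)
  if (length(frames) < 1) stop("need at least one frame")
  if (is.unsorted(grid, strictly = TRUE))
    stop("wavelength grid must be strictly increasing")
  if (!is.finite(gamma_ev) || gamma_ev <= 0) stop("gamma_ev must be > 0")
  if (is.null(states))
    states <- vapply(frames[[1]]$states, function(s) s$state_index,
                     integer(1))
  k <- photophysics_constants()
  egrid <- k$hc_eVnm / grid
  jac <- k$hc_eVnm / grid^2          # |dE/dlambda| in eV/nm
  comp <- matrix(0, length(grid), length(states),
                 dimnames = list(NULL, paste0("s", states)))
  covered <- FALSE
  for (fr in frames) {
    for (j in seq_along(states)) {
      s <- state_by_index(fr, states[j])
      if (is.null(s))
        stop("state ", states[j], " missing in frame ", fr$frame_id)
      f <- oscillator_strength(
        convert_energy(s$excitation_energy, "eV", "au_omega"), s$tdm)
      if (weighting == "photoselection") {
        nrm <- sqrt(sum(s$tdm^2))
        w <- if (nrm == 0) 0 else (sum(s$tdm * fr$membrane_normal) / nrm)^2
        f <- f * w
      }
      if (s$excitation_energy >= min(egrid) &&
          s$excitation_energy <= max(egrid)) covered <- TRUE
      comp[, j] <- comp[, j] +
        f * lineshape_density(egrid - s$excitation_energy, gamma_ev,
                              lineshape) * jac
    }
  }
  if (!covered)
    warning("no state energy falls inside the wavelength grid")
  comp <- comp / length(frames)
  out <- data.frame(wavelength_nm = grid, total = rowSums(comp))
  out <- cbind(out, as.data.frame(comp))
  structure(out, class = c("spectrum", "data.frame"),
            gamma_ev = gamma_ev, lineshape = lineshape,
            weighting = weighting, axis = "one-photon")
}

#' Integrated intensity of a spectrum
#'
#' Trapezoidal integral of the total intensity over the wavelength grid.
#' Because broadening is applied in energy space and mapped with the
#' Jacobian, this equals the energy-space integral, i.e. the ensemble-mean
#' total (weighted) oscillator strength for a one-photon spectrum on a
#' grid wide enough to capture the lineshape tails.
#'
#' @param spec a `spectrum` object.
#' @return the integral (dimensionless for OPA spectra).
#' @export
spectrum_area <- function(spec) {
  pracma::trapz(spec$wavelength_nm, spec$total)
}

#' Peak wavelength of a spectrum
#'
#' @param spec a `spectrum` object.
#' @param component column to use (default `"total"`).
#' @return wavelength (nm) of the maximum on the grid.
#' @export
spectrum_peak <- function(spec, component = "total") {
  spec$wavelength_nm[which.max(spec[[component]])]
}
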