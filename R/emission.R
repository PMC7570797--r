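#' Radiative lifetime from the spontaneous-emission rate
#'
#' The vacuum Einstein rate for a transition with dipole mu and angular
#' frequency omega,
#'
#'   Gamma0 = (4/3) * |mu|^2 / (4 pi eps0 hbar) * (omega / c)^3,
#'
#' is evaluated in SI after converting the atomic-unit dipole and the eV
#' energy.  In a medium of refractive index n the photon energy
#' renormalization gives Gamma_r = n * Gamma0, so the lifetime
#' tau = 1 / Gamma_r shortens by 1/n.
#'
#' @param tdm transition dipole moment: length-3 vector or magnitude, au.
#' @param energy_ev emission energy in eV (> 0).
#' @param refractive_index medium refractive index (>= 1, default 1).
#' @return list of class `lifetime_record`: `gamma0_s` and `gamma_r_s`
#'   (rates in 1/s), `tau_ns`, `refractive_index`, `flagged` (TRUE for a
#'   zero dipole, for which the rates vanish and the lifetime is infinite).
#' @export
#' @examples
#' radiative_lifetime(c(0, 0, 4), 3.58, 1.789)$tau_ns
radiative_lifetime <- function(tdm, energy_ev, refractive_index = 1) {
  if (!is.finite(energy_ev) || energy_ev <= 0)
    stop("emission energy must be > 0 (eV)")
  if (!is.finite(refractive_index) || refractive_index < 1)
    stop("refractive index must be >= 1")
  k <- photophysics_constants()
  mu2_au <- if (length(tdm) == 3) sum(tdm^2) else tdm^2
  flagged <- mu2_au == 0
  mu2_si <- mu2_au * k$au_dipole_Cm^2
  omega <- energy_ev * k$e_C / k$hbar
  gamma0 <- (4 / 3) * mu2_si / (4 * pi * k$eps0 * k$hbar) *
    (omega / k$c_ms)^3
  gamma_r <- refractive_index * gamma0
  structure(list(gamma0_s = gamma0, gamma_r_s = gamma_r,
                 tau_ns = if (flagged) Inf else 1 / gamma_r * 1e9,
                 refractive_index = refractive_index, flagged = flagged),
            class = "lifetime_record")
}

#' Per-frame radiative lifetimes of an ensemble
#'
#' Applies [radiative_lifetime()] to the S1 state of every frame, using
#' each frame's phase to look up the refractive index.  Emission energies
#' default to the stored (absorption) S1 energies.
#'
#' @param frames list of `frame_record` objects.
#' @param config phase configuration from [phase_config()].
#' @return data.frame: `frame_id`, `time`, `phase`, `depth`, `energy_ev`,
#'   `mu_au`, `gamma_r_s`, `tau_ns`.
#' @export
lifetime_table <- function(frames, config = phase_config()) {
  if (length(frames) < 1) stop("need at least one frame")
  rows <- lapply(frames, function(fr) {
    s <- state_by_index(fr, 1)
    if (is.null(s)) stop("S1 missing in frame ", fr$frame_id)
    n <- phase_refractive_index(config, fr$phase)
    lt <- radiative_lifetime(s$tdm, s$excitation_energy, n)
    data.frame(frame_id = fr$frame_id, time = fr$time, phase = fr$phase,
               depth = fr$depth, energy_ev = s$excitation_energy,
               mu_au = sqrt(sum(s$tdm^2)), gamma_r_s = lt$gamma_r_s,
               tau_ns = lt$tau_ns)
  })
  do.call(rbind, rows)
}

#' Cumulative average of the fluorescence decay time
#'
#' Element k is the mean radiative lifetime over frames 1..k, the running
#' average used to display ensemble convergence of the decay time.
#'
#' @inheritParams lifetime_table
#' @return data.frame `frame_id`, `tau_ns`, `cumulative_mean_ns`.
#' @export
cumulative_lifetime_trace <- function(frames, config = phase_config()) {
  tab <- lifetime_table(frames, config)
  data.frame(frame_id = tab$frame_id, tau_ns = tab$tau_ns,
             cumulative_mean_ns = cumsum(tab$tau_ns) /
               seq_along(tab$tau_ns))
}

# core anisotropy computation from unit (or unnormalized) dipole vectors
# and per-frame omega^3 mu^2 intensity weights
anisotropy_core <- function(V, weights, reference, ref_vector, mode,
                            tail_fraction) {
  n <- nrow(V)
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm == 0)) stop("zero-length transition dipole in the trace")
  U <- V / nrm
  ref <- switch(reference,
    "first-frame" = U[1, ],
    "fixed-vector" = {
      if (is.null(ref_vector)) stop("fixed-vector reference needs ref_vector")
      ref_vector / sqrt(sum(ref_vector^2))
    })
  cb <- pmin(1, pmax(-1, as.numeric(U %*% ref)))
  c2 <- cb^2
  ipar <- weights * (1 + 2 * c2)
  iperp <- weights * (2 - c2)
  if (mode == "running") {
    ipar_u <- cumsum(ipar) / seq_len(n)
    iperp_u <- cumsum(iperp) / seq_len(n)
  } else {
    ipar_u <- ipar
    iperp_u <- iperp
  }
  r <- (ipar_u - iperp_u) / (ipar_u + 2 * iperp_u)
  tail_start <- max(1L, n - floor(tail_fraction * n) + 1L)
  data_out <- data.frame(frame = seq_len(n),
                         b_deg = acos(cb) * 180 / pi,
                         i_par = ipar_u, i_perp = iperp_u, r = r)
  structure(list(trace = data_out,
                 r_limit = mean(r[tail_start:n]),
                 tail_window = c(tail_start, n), mode = mode,
                 reference = reference),
            class = "anisotropy_trace")
}

#' Fluorescence anisotropy decay over a frame sequence
#'
#' For each frame the angle b between the S1 transition dipole and a
#' reference dipole (the first frame's, by default) feeds the parallel and
#' perpendicular emission intensities
#' I_par ~ omega^3 mu^2 (1 + 2 cos^2 b), I_perp ~ omega^3 mu^2
#' (2 - cos^2 b), restricted to the S1 -> S0 channel, and the anisotropy
#' r = (I_par - I_perp) / (I_par + 2 I_perp).  With a single emitting
#' state the omega^3 mu^2 factors cancel and r = 0.4 * P2(cos b), bounded
#' by -0.2 (b = 90 deg) and 0.4 (b = 0).  In `"running"` mode the
#' intensities are cumulatively averaged before forming r, mimicking an
#' ensemble-accumulated decay curve.  The limiting anisotropy is the mean
#' of r over the final `tail_fraction` of the trace.
#'
#' @param x list of `frame_record`s, a `cone_trajectory`, or an n x 3
#'   matrix of dipole vectors.
#' @param reference `"first-frame"` (default) or `"fixed-vector"`.
#' @param ref_vector lab-frame reference dipole for
#'   `reference = "fixed-vector"`.
#' @param mode `"instantaneous"` (default) or `"running"`.
#' @param tail_fraction fraction of the trace (from the end) averaged into
#'   the limiting anisotropy (default 1/3).
#' @return list of class `anisotropy_trace`: `trace` (data.frame `frame`,
#'   `b_deg`, `i_par`, `i_perp`, `r`), `r_limit`, `tail_window`, `mode`,
#'   `reference`.
#' @export
#' @examples
#' tr <- generate_cone_trajectory(S = 0.8, seed = 2)
#' anisotropy_trace(tr)$r_limit   # ~ 0.4 * 0.64
anisotropy_trace <- function(x, reference = c("first-frame", "fixed-vector"),
                             ref_vector = NULL,
                             mode = c("instantaneous", "running"),
                             tail_fraction = 1 / 3) {
  reference <- match.arg(reference)
  mode <- match.arg(mode)
  if (inherits(x, "cone_trajectory")) {
    V <- x$vectors
    weights <- rep(1, nrow(V))
  } else if (is.matrix(x)) {
    V <- x
    weights <- rep(1, nrow(V))
  } else {
    if (length(x) < 1) stop("need at least one frame")
    V <- t(vapply(x, function(fr) {
      s <- state_by_index(fr, 1)
      if (is.null(s)) stop("S1 missing in frame ", fr$frame_id)
      s$tdm
    }, numeric(3)))
    k <- photophysics_constants()
    weights <- vapply(x, function(fr) {
      s <- state_by_index(fr, 1)
      (s$excitation_energy / k$hartree_eV)^3 * sum(s$tdm^2)
    }, numeric(1))
  }
  anisotropy_core(V, weights, reference, ref_vector, mode, tail_fraction)
}

#' Depth-lifetime correlation table
#'
#' Pairs each frame's probe depth (distance of the probe's center of mass
#' from the phosphorus plane) with its radiative lifetime, plus per-phase
#' min-max ranges of both quantities: a narrow depth spread with a wide
#' lifetime spread (or vice versa) distinguishes the membrane phases.
#'
#' @inheritParams lifetime_table
#' @return list with `table` (frame_id, phase, depth_nm, tau_ns) and
#'   `summary` (per phase: depth_min, depth_max, tau_min, tau_max).
#' @export
depth_lifetime_table <- function(frames, config = phase_config()) {
  tab <- lifetime_table(frames, config)
  out <- data.frame(frame_id = tab$frame_id, phase = tab$phase,
                    depth_nm = tab$depth, tau_ns = tab$tau_ns)
  sm <- do.call(rbind, lapply(split(out, out$phase), function(d) {
    data.frame(phase = d$phase[1],
               depth_min = min(d$depth_nm), depth_max = max(d$depth_nm),
               tau_min = min(d$tau_ns), tau_max = max(d$tau_ns))
  }))
  rownames(sm) <- NULL
  list(table = out, summary = sm)
}
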