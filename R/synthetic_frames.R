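#' Built-in phase presets for the synthetic frame generator
#'
#' Each preset encodes the phase-specific statistical structure seen for
#' the probe in snapshot ensembles of the three membranes:
#' \describe{
#'   \item{DPPC (solid gel)}{single transition-dipole orientation near 36
#'     degrees to the membrane normal, narrow S1 absorption around 346 nm,
#'     probe depth uniform over 1.1-1.6 nm, short radiative lifetime
#'     (mean 0.69 ns), strongest two-photon and hyper-Rayleigh response.}
#'   \item{DOPC (liquid disordered)}{bimodal orientation (40 and 140
#'     degrees, the two lobes being the same orientation by molecular
#'     symmetry, i.e. probe flip-flops), S1 near 336 nm, depth 1.3-2.1 nm,
#'     lifetime mean 0.87 ns, weak S1 two-photon response but strong S2.}
#'   \item{SMCHOL (liquid ordered, 2:1 SM/cholesterol)}{dominant
#'     orientation near 160 degrees plus a subpopulation of 8 of 40 frames
#'     perpendicular to the normal (occupying frame indices 5-12), much
#'     broader absorption, narrow depth around 1.1 nm but a wide lifetime
#'     spread (0.7-1.2 ns), wandering outer dihedrals (dh3, dh5, dh7).}
#' }
#'
#' @param phase `"DOPC"`, `"DPPC"` or `"SMCHOL"`.
#' @param n_frames number of frames (default 40).
#' @param seed integer RNG seed stored in the preset.
#' @return a list of class `phase_preset`; pass to
#'   [generate_phase_frames()].  Any element may be overridden before
#'   generation.
#' @export
builtin_preset <- function(phase = c("DOPC", "DPPC", "SMCHOL"),
                           n_frames = 40, seed = 1L) {
  phase <- match.arg(toupper(phase), c("DOPC", "DPPC", "SMCHOL"))
  base <- list(
    phase = phase, n_frames = as.integer(n_frames), seed = as.integer(seed),
    # S2/S3 sit blue of S1 (their two-photon wavelengths fall in the
    # 620-630 nm band); small magnitudes keep them one-photon dark
    state_energy_offsets = c(S2 = 0.40, S3 = 0.46),
    dark_state_tdm = list(mean = 0.35, sd = 0.05),
    beta_dynamic_factor = 10,
    time_start = 305, time_step = 5)
  ph <- switch(phase,
    DPPC = list(
      tdm_angle_model = list(kind = "unimodal", mean = 36, sd = 5),
      azimuth_model = list(kind = "walk", step_sd_deg = 4),
      wavelength_model = list(mean = 346, sd = 2.5),
      delta_model = list(S1 = c(6380, 600), S2 = c(4300, 600),
                         S3 = c(4170, 600)),
      beta_scale = 5030,
      lifetime_model = list(kind = "normal", mean = 0.69, sd = 0.02),
      depth_model = list(kind = "uniform", min = 1.1, max = 1.6),
      dihedral_model = list(kind = "fixed_trans", jitter_sd = 5)),
    DOPC = list(
      tdm_angle_model = list(kind = "bimodal", means = c(40, 140),
                             sds = c(8, 8), weights = c(0.5, 0.5),
                             switch_prob = 0.1),
      azimuth_model = list(kind = "walk", step_sd_deg = 12),
      wavelength_model = list(mean = 336, sd = 3),
      delta_model = list(S1 = c(900, 150), S2 = c(10600, 1200),
                         S3 = c(5200, 800)),
      beta_scale = 1400,
      lifetime_model = list(kind = "normal", mean = 0.87, sd = 0.03),
      depth_model = list(kind = "uniform", min = 1.3, max = 2.1),
      dihedral_model = list(kind = "fixed_trans", jitter_sd = 6)),
    SMCHOL = list(
      tdm_angle_model = list(kind = "main_plus_sub", main_mean = 160,
                             main_sd = 6, sub_mean = 90, sub_sd = 1.5,
                             sub_count = 8, sub_start = 5),
      azimuth_model = list(kind = "independent"),
      wavelength_model = list(mean = 337, sd = 9),
      delta_model = list(S1 = c(5050, 700), S2 = c(4100, 600),
                         S3 = c(3980, 500),
                         sub_S1 = c(2020, 300), sub_S3_factor = 5),
      beta_scale = 1960,
      lifetime_model = list(kind = "uniform", min = 0.7, max = 1.2),
      depth_model = list(kind = "normal", mean = 1.1, sd = 0.05),
      dihedral_model = list(kind = "wandering",
                            wander_sd = c(dh3 = 25, dh5 = 70, dh7 = 90),
                            jitter_sd = 6)))
  preset <- c(base, ph)
  class(preset) <- "phase_preset"
  preset
}

# draw polar angles (degrees, in [0, 180]) from a preset angle model;
# out-of-range draws are reflected back into [0, 180]
draw_tdm_angles <- function(model, n) {
  ang <- switch(model$kind,
    unimodal = stats::rnorm(n, model$mean, model$sd),
    bimodal = {
      # lobe occupancy is persistent in time when switch_prob is given
      # (the two lobes are flip-flopped copies of one orientation, and
      # flips are sporadic events along a trajectory)
      if (is.null(model$switch_prob)) {
        comp <- sample.int(length(model$means), n, replace = TRUE,
                           prob = model$weights)
      } else {
        comp <- integer(n)
        comp[1] <- sample.int(length(model$means), 1, prob = model$weights)
        flip <- stats::runif(n - 1) < model$switch_prob
        for (i in seq_len(n - 1))
          comp[i + 1] <- if (flip[i]) 3L - comp[i] else comp[i]
      }
      stats::rnorm(n, model$means[comp], model$sds[comp])
    },
    main_plus_sub = {
      a <- stats::rnorm(n, model$main_mean, model$main_sd)
      sub <- seq(model$sub_start, length.out = model$sub_count)
      a[sub] <- stats::rnorm(model$sub_count, model$sub_mean, model$sub_sd)
      a
    },
    stop("unknown tdm angle model: ", model$kind))
  ang <- abs(ang)
  ang[ang > 180] <- 360 - ang[ang > 180]
  ang
}

# azimuth about the membrane normal: either memoryless between frames or
# a random walk, which preserves orientation memory along the sequence
# (hindered in-plane rotation) without changing the angle-to-normal model
draw_azimuths <- function(model, n) {
  if (is.null(model) || identical(model$kind, "independent"))
    return(stats::runif(n, 0, 2 * pi))
  step <- model$step_sd_deg * pi / 180
  stats::runif(1, 0, 2 * pi) +
    c(0, cumsum(stats::rnorm(n - 1, 0, step)))
}

draw_positive <- function(n, mean, sd) {
  pmax(stats::rnorm(n, mean, sd), 0)
}

# |mu| (au) that yields lifetime tau_ns at energy_ev in medium n:
# inversion of the spontaneous-emission rate law
mu_from_lifetime <- function(tau_ns, energy_ev, n_medium) {
  k <- photophysics_constants()
  omega <- energy_ev * k$e_C / k$hbar
  pref <- (4 / 3) / (4 * pi * k$eps0 * k$hbar) * (omega / k$c_ms)^3
  mu2_si <- 1 / (tau_ns * 1e-9 * n_medium * pref)
  sqrt(mu2_si) / k$au_dipole_Cm
}

#' Generate a synthetic frame ensemble for one membrane phase
#'
#' Realizes a [builtin_preset()] (or a user-modified copy) as a list of
#' valid `frame_record`s.  Transition-dipole directions are drawn by
#' sampling the polar angle from the preset's orientation model and a
#' uniform azimuth about the membrane normal (+z).  The S1 dipole
#' magnitude is obtained by inverting the spontaneous-emission rate law at
#' the drawn excitation energy, the phase's refractive index and a
#' lifetime drawn from the preset's lifetime model, so that the emission
#' stage recovers the preset lifetimes by construction.  Hyperpolarizability
#' tensors have a dominant zzz component at the preset's `beta_scale` with
#' small random off-components; the dynamic tensor is the static one scaled
#' by `beta_dynamic_factor`.  Identical seeds give identical output.
#'
#' @param preset a `phase_preset`.
#' @param config phase configuration from [phase_config()] (for the
#'   refractive index used in the lifetime inversion).
#' @return list of `frame_record` objects of length `preset$n_frames`.
#' @export
#' @examples
#' frames <- generate_phase_frames(builtin_preset("DPPC", seed = 7))
#' length(frames)
generate_phase_frames <- function(preset, config = phase_config()) {
  stopifnot(inherits(preset, "phase_preset") || is.list(preset))
  n <- preset$n_frames
  if (is.null(n) || n < 1) stop("infeasible preset: n_frames must be >= 1")
  for (m in list(preset$wavelength_model$sd, preset$dark_state_tdm$sd))
    if (!is.null(m) && m < 0) stop("infeasible preset: negative sd")
  n_medium <- phase_refractive_index(config, preset$phase)
  withr::with_seed(preset$seed, {
    theta <- draw_tdm_angles(preset$tdm_angle_model, n)
    phi <- draw_azimuths(preset$azimuth_model, n)
    lam1 <- draw_positive(n, preset$wavelength_model$mean,
                          preset$wavelength_model$sd)
    e1 <- convert_energy(lam1, "nm", "eV")
    e2 <- e1 + preset$state_energy_offsets[["S2"]]
    e3 <- e1 + preset$state_energy_offsets[["S3"]]
    lm <- preset$lifetime_model
    tau <- switch(lm$kind,
      normal = pmax(stats::rnorm(n, lm$mean, lm$sd), 0.05),
      uniform = stats::runif(n, lm$min, lm$max),
      stop("unknown lifetime model: ", lm$kind))
    mu1 <- mu_from_lifetime(tau, e1, n_medium)
    mu_dark <- matrix(draw_positive(2 * n, preset$dark_state_tdm$mean,
                                    preset$dark_state_tdm$sd), ncol = 2)
    dm <- preset$delta_model
    d1 <- draw_positive(n, dm$S1[1], dm$S1[2])
    d2 <- draw_positive(n, dm$S2[1], dm$S2[2])
    d3 <- draw_positive(n, dm$S3[1], dm$S3[2])
    sub_idx <- integer(0)
    if (identical(preset$tdm_angle_model$kind, "main_plus_sub")) {
      sub_idx <- seq(preset$tdm_angle_model$sub_start,
                     length.out = preset$tdm_angle_model$sub_count)
      if (!is.null(dm$sub_S1))
        d1[sub_idx] <- draw_positive(length(sub_idx), dm$sub_S1[1],
                                     dm$sub_S1[2])
      if (!is.null(dm$sub_S3_factor))
        d3[sub_idx] <- d3[sub_idx] * dm$sub_S3_factor
    }
    depm <- preset$depth_model
    depth <- switch(depm$kind,
      uniform = stats::runif(n, depm$min, depm$max),
      normal = stats::rnorm(n, depm$mean, depm$sd),
      stop("unknown depth model: ", depm$kind))
    dihedrals <- draw_dihedrals(preset$dihedral_model, n)
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      th <- theta[i] * pi / 180
      dir1 <- c(sin(th) * cos(phi[i]), sin(th) * sin(phi[i]), cos(th))
      # dark-state dipoles: random directions, small magnitude
      dark_dirs <- random_unit_vectors(2)
      states <- list(
        excited_state(1, e1[i], mu1[i] * dir1, d1[i]),
        excited_state(2, e2[i], mu_dark[i, 1] * dark_dirs[1, ], d2[i]),
        excited_state(3, e3[i], mu_dark[i, 2] * dark_dirs[2, ], d3[i]))
      bstat <- random_beta_components(preset$beta_scale)
      frames[[i]] <- frame_record(
        frame_id = i, time = preset$time_start + (i - 1) * preset$time_step,
        phase = preset$phase, membrane_normal = c(0, 0, 1),
        depth = depth[i], dihedrals = dihedrals[i, ], states = states,
        beta_static = beta_tensor(bstat, "static"),
        beta_dynamic = beta_tensor(bstat * preset$beta_dynamic_factor,
                                   "dynamic", wavelength = 810))
    }
    frames
  })
}

# all-trans backbone reference pattern: dh7 is defined with respect to the
# opposite carbon of its phenyl ring, so the all-trans conformer reads cis
# on dh7
DIHEDRAL_BASE <- c(180, 180, 180, 180, 180, 180, 0)

draw_dihedrals <- function(model, n) {
  jit <- matrix(stats::rnorm(7 * n, 0, model$jitter_sd), nrow = n)
  ang <- sweep(jit, 2, DIHEDRAL_BASE, `+`)
  if (identical(model$kind, "wandering")) {
    for (nm in names(model$wander_sd)) {
      j <- as.integer(sub("dh", "", nm))
      ang[, j] <- DIHEDRAL_BASE[j] + stats::rnorm(n, 0, model$wander_sd[[nm]])
    }
  }
  wrap_angle(ang)
}

random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# dominant-zzz tensor with ~5% random off-diagonal structure
random_beta_components <- function(scale) {
  b <- array(stats::rnorm(27, 0, 0.05 * scale), dim = c(3, 3, 3))
  b[3, 3, 3] <- scale * (1 + 0.1 * stats::rnorm(1))
  b
}

#' Generate a wobbling-in-cone transition-dipole trajectory
#'
#' Test harness for the anisotropy machinery: a stationary unit-vector
#' process whose long-time fluorescence anisotropy tends to the closed-form
#' cone-model limit r_inf = 0.4 * S^2.
#'
#' For 0 < S < 1 the dipole lives on the cone surface at the fixed polar
#' angle theta* with P2(cos theta*) = S, i.e. cos theta* =
#' sqrt((2S + 1) / 3), and performs azimuthal Brownian motion with angular
#' diffusion coefficient `rate` (rad^2/ns).  Averaging the second Legendre
#' polynomial of the angle to the (cone-resident) initial dipole over the
#' decorrelated azimuth gives exactly S^2 by the spherical-harmonic
#' addition theorem.  S = 1 freezes the dipole; S = 0 switches to isotropic
#' rotational diffusion on the sphere.
#'
#' @param S orientational order parameter in \[0, 1\].
#' @param rate angular diffusion coefficient in rad^2/ns.
#' @param n_steps number of steps (>= 2).
#' @param dt time step in ns.
#' @param seed integer RNG seed.
#' @return list of class `cone_trajectory` with elements `time` (ns),
#'   `vectors` (n_steps x 3 matrix of unit vectors), `S`, `rate`.
#' @export
generate_cone_trajectory <- function(S, rate = 10, n_steps = 2000,
                                     dt = 0.05, seed = 1L) {
  if (!is.finite(S) || S < 0 || S > 1)
    stop("order parameter S must lie in [0, 1]")
  if (n_steps < 2) stop("n_steps must be >= 2")
  time <- (seq_len(n_steps) - 1) * dt
  V <- withr::with_seed(seed, {
    if (S == 1) {
      matrix(rep(c(0, 0, 1), each = n_steps), ncol = 3)
    } else if (S == 0) {
      # tangent-space Euler-Maruyama rotational diffusion on the sphere
      V <- matrix(0, n_steps, 3)
      v <- random_unit_vectors(1)[1, ]
      V[1, ] <- v
      sig <- sqrt(2 * rate * dt)
      for (i in 2:n_steps) {
        xi <- stats::rnorm(3, 0, sig)
        v <- v + (xi - sum(xi * v) * v)
        v <- v / sqrt(sum(v^2))
        V[i, ] <- v
      }
      V
    } else {
      cth <- sqrt((2 * S + 1) / 3)
      sth <- sqrt(1 - cth^2)
      phi <- stats::runif(1, 0, 2 * pi) +
        c(0, cumsum(stats::rnorm(n_steps - 1, 0, sqrt(2 * rate * dt))))
      cbind(sth * cos(phi), sth * sin(phi), rep(cth, n_steps))
    }
  })
  structure(list(time = time, vectors = V, S = S, rate = rate, seed = seed),
            class = "cone_trajectory")
}
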