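#' Two-photon absorption cross section in Goeppert-Mayer units
#'
#' Converts an atomic-unit two-photon strength delta into a cross section
#' at the peak of a Lorentzian line of full width Gamma:
#'
#'   sigma(GM) = 8 pi^2 alpha^2 a0^4 t0 * (omega/2)^2 * delta / Gamma
#'
#' with omega the one-photon excitation energy and omega, delta, Gamma in
#' atomic units; a0^4 t0 carries the cm^4 s dimension of the cross section
#' (1 GM = 1e-50 cm^4 s / photon).  Each of the two absorbed photons
#' carries half the transition energy, hence the (omega/2)^2 factor.
#' sigma is linear in delta, quadratic in omega, and zero for delta = 0.
#'
#' @param delta two-photon strength in au (>= 0); vectorized.
#' @param energy_ev one-photon excitation energy in eV (> 0).
#' @param gamma_ev Lorentzian broadening (FWHM) in eV, default 0.1.
#' @return cross section(s) in GM.
#' @export
#' @examples
#' tpa_cross_section(6400, convert_energy(346, "nm", "eV"))  # ~60 GM
tpa_cross_section <- function(delta, energy_ev, gamma_ev = 0.1) {
  if (any(!is.finite(energy_ev) | energy_ev <= 0))
    stop("excitation energy must be > 0")
  if (!is.finite(gamma_ev) || gamma_ev <= 0)
    stop("gamma_ev must be > 0")
  if (any(delta < 0)) stop("delta must be >= 0")
  k <- photophysics_constants()
  omega <- energy_ev / k$hartree_eV
  gam <- gamma_ev / k$hartree_eV
  8 * pi^2 * k$alpha^2 * k$gm_per_au_area_time * (omega / 2)^2 * delta / gam
}

#' Per-state two-photon absorption spectrum and cross-section table
#'
#' Evaluates [tpa_cross_section()] for every (frame, state) and aggregates
#' the ensemble on the two-photon wavelength axis (twice the one-photon
#' wavelength).  Spectral values are in GM: each contribution is the
#' frame's cross section times a peak-normalized lineshape in transition-
#' energy space, averaged over frames, so a delta-free frame contributes
#' nothing and a single frame's spectrum peaks at its own sigma.
#'
#' @inheritParams broadened_spectrum
#' @param grid increasing two-photon wavelength grid in nm.
#' @return list with `spectrum` (a `spectrum` object on the two-photon
#'   axis, GM units) and `points` (data.frame `frame_id`, `state_index`,
#'   `wavelength_nm`, `cross_section_gm`, sorted by frame then state).
#' @export
tpa_spectrum <- function(frames, states = NULL, grid,
                         gamma_ev = 0.1,
                         lineshape = c("lorentzian", "gaussian")) {
  lineshape <- match.arg(lineshape)
  if (length(frames) < 1) stop("need at least one frame")
  if (is.unsorted(grid, strictly = TRUE))
    stop("wavelength grid must be strictly increasing")
  if (is.null(states))
    states <- vapply(frames[[1]]$states, function(s) s$state_index,
                     integer(1))
  k <- photophysics_constants()
  # transition energy corresponding to each two-photon grid wavelength
  egrid <- 2 * k$hc_eVnm / grid
  peak <- lineshape_density(0, gamma_ev, lineshape)
  comp <- matrix(0, length(grid), length(states),
                 dimnames = list(NULL, paste0("s", states)))
  pts <- vector("list", length(frames) * length(states))
  n <- 0L
  for (fr in frames) {
    for (j in seq_along(states)) {
      s <- state_by_index(fr, states[j])
      if (is.null(s))
        stop("state ", states[j], " missing in frame ", fr$frame_id)
      sig <- tpa_cross_section(s$tpa_strength_delta, s$excitation_energy,
                               gamma_ev)
      comp[, j] <- comp[, j] + sig *
        lineshape_density(egrid - s$excitation_energy, gamma_ev,
                          lineshape) / peak
      n <- n + 1L
      pts[[n]] <- data.frame(
        frame_id = fr$frame_id, state_index = states[j],
        wavelength_nm = 2 * convert_energy(s$excitation_energy, "eV", "nm"),
        cross_section_gm = sig)
    }
  }
  comp <- comp / length(frames)
  points <- do.call(rbind, pts)
  points <- points[order(points$frame_id, points$state_index), ]
  rownames(points) <- NULL
  spec <- data.frame(wavelength_nm = grid, total = rowSums(comp))
  spec <- cbind(spec, as.data.frame(comp))
  spec <- structure(spec, class = c("spectrum", "data.frame"),
                    gamma_ev = gamma_ev, lineshape = lineshape,
                    weighting = "none", axis = "two-photon")
  list(spectrum = spec, points = points)
}

# sum over the 15 pairings of six indices of delta-contractions of
# beta (x) beta: the exact isotropic average of Z_i...Z_n is
# (1/105) * this sum
beta_pairing_sum <- function(B) {
  pairings <- list(
    list(c(1,2), c(3,4), c(5,6)), list(c(1,2), c(3,5), c(4,6)),
    list(c(1,2), c(3,6), c(4,5)), list(c(1,3), c(2,4), c(5,6)),
    list(c(1,3), c(2,5), c(4,6)), list(c(1,3), c(2,6), c(4,5)),
    list(c(1,4), c(2,3), c(5,6)), list(c(1,4), c(2,5), c(3,6)),
    list(c(1,4), c(2,6), c(3,5)), list(c(1,5), c(2,3), c(4,6)),
    list(c(1,5), c(2,4), c(3,6)), list(c(1,5), c(2,6), c(3,4)),
    list(c(1,6), c(2,3), c(4,5)), list(c(1,6), c(2,4), c(3,5)),
    list(c(1,6), c(2,5), c(3,4)))
  vals <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
  total <- 0
  for (p in pairings) {
    s <- 0
    for (r in seq_len(nrow(vals))) {
      idx <- integer(6)
      for (q in 1:3) idx[p[[q]]] <- vals[r, q]
      s <- s + B[idx[1], idx[2], idx[3]] * B[idx[4], idx[5], idx[6]]
    }
    total <- total + s
  }
  total
}

#' Hyper-Rayleigh scattering response by exact orientational averaging
#'
#' The isotropic orientational averages of the lab-frame squared
#' hyperpolarizability components are evaluated exactly for a general
#' (no Kleinman symmetry assumed) 27-component molecular tensor:
#'
#' * `<beta^2_ZZZ>` = (1/105) * sum over the 15 pair contractions of
#'   beta (x) beta (the rank-6 isotropic moment of a uniformly random
#'   unit vector);
#' * `<beta^2_XZZ>` = ( <|A|^2> - <beta^2_ZZZ> ) / 2 with
#'   A_i(Z) = beta_ijk Z_j Z_k and
#'   `<|A|^2>` = (1/15) * (sum_i (sum_j beta_ijj)^2 + sum beta_ijk^2 +
#'   sum beta_ijk beta_ikj), using the rank-4 isotropic moment and the
#'   fact that the lab X axis is uniform on the circle orthogonal to Z.
#'
#' The scalar HRS response is beta_HRS = sqrt(<beta^2_ZZZ> +
#' <beta^2_XZZ>) and the depolarization ratio <beta^2_ZZZ> /
#' <beta^2_XZZ> (5 for a single-component beta_zzz tensor, for which
#' beta_HRS = |beta_zzz| * sqrt(6/35)).
#'
#' @param B a [beta_tensor()] (or any 3x3x3 numeric array), atomic units.
#' @return list of class `hrs_result`: `b2_zzz`, `b2_xzz` (au^2),
#'   `beta_hrs` (au), `beta_hrs_esu30` (units of 1e-30 esu),
#'   `depolarization` and the tensor's `regime`.
#' @export
#' @examples
#' B <- array(0, c(3, 3, 3)); B[3, 3, 3] <- 100
#' beta_hrs_analytic(B)$beta_hrs / 100  # sqrt(6/35) = 0.4140
beta_hrs_analytic <- function(B) {
  regime <- attr(B, "regime")
  B <- array(as.numeric(B), dim = c(3, 3, 3))
  if (any(!is.finite(B))) stop("beta tensor must have 27 finite components")
  b2_zzz <- beta_pairing_sum(B) / 105
  trace_vec <- vapply(1:3, function(i) sum(diag(B[i, , ])), numeric(1))
  c1 <- sum(trace_vec^2)
  c2 <- sum(B^2)
  c3 <- sum(B * aperm(B, c(1, 3, 2)))
  mean_a2 <- (c1 + c2 + c3) / 15
  b2_xzz <- (mean_a2 - b2_zzz) / 2
  hrs_result(b2_zzz, b2_xzz, regime)
}

hrs_result <- function(b2_zzz, b2_xzz, regime = NULL, se = NULL) {
  k <- photophysics_constants()
  beta_hrs <- sqrt(b2_zzz + b2_xzz)
  out <- list(b2_zzz = b2_zzz, b2_xzz = b2_xzz, beta_hrs = beta_hrs,
              beta_hrs_esu30 = beta_hrs * k$beta_au_esu * 1e30,
              depolarization = if (b2_xzz > 0) b2_zzz / b2_xzz else NA_real_,
              regime = if (is.null(regime)) NA_character_ else regime)
  if (!is.null(se)) out$mc_se <- se
  class(out) <- "hrs_result"
  out
}

#' @export
print.hrs_result <- function(x, ...) {
  cat(sprintf(
    "<hrs_result%s> beta_HRS = %.4g au (%.4g x 1e-30 esu), DR = %.3f%s\n",
    if (!is.na(x$regime)) paste0(" ", x$regime) else "",
    x$beta_hrs, x$beta_hrs_esu30, x$depolarization,
    if (!is.null(x$mc_se)) sprintf(" (MC se on beta: %.2g au)", x$mc_se)
    else ""))
  invisible(x)
}

#' Uniformly random rotation matrices
#'
#' Draws rotations uniformly over SO(3) by normalizing 4-vectors of
#' standard normals to unit quaternions.
#'
#' @param n number of rotations.
#' @return a 3 x 3 x n array of proper rotation matrices.
#' @export
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  R <- array(0, c(3, 3, n))
  R[1, 1, ] <- 1 - 2 * (y^2 + z^2)
  R[1, 2, ] <- 2 * (x * y - w * z)
  R[1, 3, ] <- 2 * (x * z + w * y)
  R[2, 1, ] <- 2 * (x * y + w * z)
  R[2, 2, ] <- 1 - 2 * (x^2 + z^2)
  R[2, 3, ] <- 2 * (y * z - w * x)
  R[3, 1, ] <- 2 * (x * z - w * y)
  R[3, 2, ] <- 2 * (y * z + w * x)
  R[3, 3, ] <- 1 - 2 * (x^2 + y^2)
  R
}

#' Rotate a hyperpolarizability tensor
#'
#' beta'_ijk = R_ia R_jb R_kc beta_abc.
#'
#' @param B 3x3x3 numeric array.
#' @param R 3x3 proper rotation matrix.
#' @return the rotated 3x3x3 array (attributes preserved).
#' @export
rotate_beta <- function(B, R) {
  out <- array(as.numeric(B), dim = c(3, 3, 3))
  # contract one index at a time
  m <- matrix(out, nrow = 3)               # a x (bc)
  out <- array(R %*% m, dim = c(3, 3, 3))  # i x (bc)
  out <- aperm(out, c(2, 1, 3))            # b x i x c
  m <- matrix(out, nrow = 3)
  out <- array(R %*% m, dim = c(3, 3, 3))  # j x i x c
  out <- aperm(out, c(3, 2, 1))            # c x i x j
  m <- matrix(out, nrow = 3)
  out <- array(R %*% m, dim = c(3, 3, 3))  # k x i x j
  out <- aperm(out, c(2, 3, 1))            # i x j x k
  attributes(out) <- attributes(B)
  dim(out) <- c(3, 3, 3)
  out
}

#' Monte-Carlo orientational average of the HRS response
#'
#' Independent numerical oracle for [beta_hrs_analytic()]: averages the
#' squared lab-frame components beta_ZZZ and beta_XZZ over uniformly
#' random rotations of the molecular tensor and reports the Monte-Carlo
#' standard errors.
#'
#' @param B a 3x3x3 hyperpolarizability array, atomic units.
#' @param n_orientations number of random rotations (default 1e5).
#' @param seed integer RNG seed.
#' @return an `hrs_result` with element `mc_se` (standard error on
#'   beta_HRS) plus `se_b2_zzz`, `se_b2_xzz`.
#' @export
beta_hrs_numeric <- function(B, n_orientations = 1e5, seed = 1L) {
  stopifnot(n_orientations >= 1)
  regime <- attr(B, "regime")
  B <- array(as.numeric(B), dim = c(3, 3, 3))
  withr::with_seed(seed, {
    R <- random_rotations(n_orientations)
    Zr <- t(R[3, , ])   # n x 3: lab-Z row of each rotation
    Xr <- t(R[1, , ])   # n x 3: lab-X row
    # W[n, (j,k)] = Z_j Z_k; A[n, i] = beta_ijk Z_j Z_k
    W <- Zr[, rep(1:3, times = 3)] * Zr[, rep(1:3, each = 3)]
    Bm <- matrix(B, nrow = 3)  # i x (jk), column-major: j fastest
    # columns of W are (j,k) with j fastest to match Bm's layout
    A <- W %*% t(Bm)
    bzzz <- rowSums(A * Zr)
    bxzz <- rowSums(A * Xr)
    z2 <- bzzz^2
    x2 <- bxzz^2
    b2_zzz <- mean(z2)
    b2_xzz <- mean(x2)
    se_z <- stats::sd(z2) / sqrt(n_orientations)
    se_x <- stats::sd(x2) / sqrt(n_orientations)
    s <- z2 + x2
    se_sum <- stats::sd(s) / sqrt(n_orientations)
    out <- hrs_result(b2_zzz, b2_xzz, regime,
                      se = se_sum / (2 * sqrt(mean(s))))
    out$se_b2_zzz <- se_z
    out$se_b2_xzz <- se_x
    out
  })
}

#' Ensemble hyper-Rayleigh scattering report
#'
#' Per-frame analytic HRS responses for the requested regime(s) plus the
#' ensemble mean and standard deviation in units of 1e-30 esu.  Frames
#' without a dynamic tensor make the dynamic regime unavailable: the
#' report then carries `available = FALSE` rather than failing.
#'
#' @param frames list of `frame_record` objects.
#' @param regime `"static"`, `"dynamic"` or `"both"`.
#' @return list of class `hrs_report` with per-regime elements `table`
#'   (frame_id, b2_zzz, b2_xzz, beta_hrs_au, beta_hrs_esu30,
#'   depolarization, running mean), `mean_esu30`, `sd_esu30`,
#'   `available`; and `dynamic_static_ratio` when both are available.
#' @export
hrs_report <- function(frames, regime = c("static", "dynamic", "both")) {
  regime <- match.arg(regime)
  want <- if (regime == "both") c("static", "dynamic") else regime
  out <- list()
  for (rg in want) {
    field <- paste0("beta_", rg)
    tensors <- lapply(frames, `[[`, field)
    if (any(vapply(tensors, is.null, logical(1)))) {
      out[[rg]] <- list(available = FALSE,
                        message = paste0(rg, " hyperpolarizability not ",
                                         "available in all frames"))
      next
    }
    rows <- mapply(function(fr, B) {
      h <- beta_hrs_analytic(B)
      data.frame(frame_id = fr$frame_id, b2_zzz = h$b2_zzz,
                 b2_xzz = h$b2_xzz, beta_hrs_au = h$beta_hrs,
                 beta_hrs_esu30 = h$beta_hrs_esu30,
                 depolarization = h$depolarization)
    }, frames, tensors, SIMPLIFY = FALSE)
    tab <- do.call(rbind, rows)
    tab$running_mean_esu30 <- cumsum(tab$beta_hrs_esu30) /
      seq_len(nrow(tab))
    out[[rg]] <- list(available = TRUE, table = tab,
                      mean_esu30 = mean(tab$beta_hrs_esu30),
                      sd_esu30 = stats::sd(tab$beta_hrs_esu30))
  }
  if (regime == "both" && isTRUE(out$static$available) &&
      isTRUE(out$dynamic$available)) {
    out$dynamic_static_ratio <- out$dynamic$mean_esu30 / out$static$mean_esu30
  }
  class(out) <- "hrs_report"
  out
}
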