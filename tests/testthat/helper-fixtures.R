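# shared fixtures built in code

make_state <- function(idx = 1, energy = 3.6, tdm = c(0, 0, 4), delta = 5000) {
  excited_state(idx, energy, tdm, delta)
}

make_frame <- function(frame_id = 1, angle_deg = 36, mu = 4, energy = 3.6,
                       phase = "DPPC", depth = 1.3, delta = 5000,
                       beta = NULL, beta_dyn = NULL) {
  th <- angle_deg * pi / 180
  tdm <- mu * c(sin(th), 0, cos(th))
  frame_record(frame_id, time = frame_id, phase = phase,
               membrane_normal = c(0, 0, 1), depth = depth,
               dihedrals = c(180, 180, 180, 180, 180, 180, 0),
               states = list(make_state(1, energy, tdm, delta),
                             make_state(2, energy + 0.4, c(0.3, 0, 0), 4000)),
               beta_static = beta, beta_dynamic = beta_dyn)
}

random_beta <- function(scale = 1) {
  array(stats::rnorm(27, 0, scale), dim = c(3, 3, 3))
}

single_zzz_beta <- function(b = 1) {
  B <- array(0, c(3, 3, 3))
  B[3, 3, 3] <- b
  B
}

# independent brute-force orbit enumeration of cis/trans codes under
# string reversal (oracle for enumerate_conformers)
orbit_count_oracle <- function(n_sites) {
  codes <- apply(do.call(expand.grid, rep(list(c("t", "c")), n_sites)),
                 1, paste0, collapse = "")
  seen <- character(0)
  orbits <- list()
  for (cd in codes) {
    rv <- paste(rev(strsplit(cd, "")[[1]]), collapse = "")
    if (cd %in% seen) next
    orbits[[length(orbits) + 1]] <- unique(c(cd, rv))
    seen <- c(seen, cd, rv)
  }
  orbits
}
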