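test_that("TPA conversion is linear in delta, quadratic in omega, zero at zero", {
  e <- convert_energy(346, "nm", "eV")
  expect_equal(tpa_cross_section(0, e), 0)
  expect_equal(tpa_cross_section(2000, e) / tpa_cross_section(1000, e), 2)
  expect_equal(tpa_cross_section(1000, 2 * e) / tpa_cross_section(1000, e),
               4, tolerance = 1e-12)
  # halving the broadening doubles the peak cross section
  expect_equal(tpa_cross_section(1000, e, 0.05) /
                 tpa_cross_section(1000, e, 0.1), 2, tolerance = 1e-12)
  expect_error(tpa_cross_section(100, -1), "> 0")
  expect_error(tpa_cross_section(-5, e), ">= 0")
})

test_that("TPA constant matches an independent SI constant assembly", {
  # oracle: assemble sigma in cm^4 s from CODATA SI values, then to GM
  alpha <- 7.2973525693e-3
  a0_cm <- 5.29177210903e-9
  t0_s <- 2.4188843265857e-17
  hartree_eV <- 27.211386245988
  delta <- 5300; lam <- 690 * 2   # one-photon 345 nm
  e_ev <- 1239.841984 / 345
  omega_au <- e_ev / hartree_eV
  gamma_au <- 0.1 / hartree_eV
  sigma_cm4s <- 8 * pi^2 * alpha^2 * a0_cm^4 * t0_s *
    (omega_au / 2)^2 * delta / gamma_au
  oracle_gm <- sigma_cm4s * 1e50
  expect_equal(tpa_cross_section(delta, e_ev, 0.1), oracle_gm,
               tolerance = 1e-6)
})

test_that("TPA spectra sit on the doubled wavelength axis with per-frame points", {
  fr <- make_frame(1, energy = convert_energy(346, "nm", "eV"),
                   delta = 6400)
  out <- tpa_spectrum(list(fr), states = 1, grid = seq(600, 800, by = 0.5))
  expect_equal(out$points$wavelength_nm, 2 * 346, tolerance = 1e-9)
  expect_equal(spectrum_peak(out$spectrum), 692, tolerance = 0.5)
  # spectrum peak carries the frame's cross section (peak-normalized line)
  expect_equal(max(out$spectrum$total),
               tpa_cross_section(6400, convert_energy(346, "nm", "eV")),
               tolerance = 1e-3)
  # zero-delta frames give a zero spectrum
  fr0 <- make_frame(1, delta = 0)
  fr0$states[[2]]$tpa_strength_delta <- 0
  out0 <- tpa_spectrum(list(fr0), grid = seq(600, 800, by = 1))
  expect_equal(max(out0$spectrum$total), 0)
})

test_that("liquid-ordered subpopulation frames show the S3 enhancement", {
  frames <- generate_phase_frames(builtin_preset("SMCHOL", seed = 13))
  out <- tpa_spectrum(frames, grid = seq(550, 800, by = 1))
  p3 <- out$points[out$points$state_index == 3, ]
  sub <- p3$cross_section_gm[p3$frame_id %in% 5:12]
  rest <- p3$cross_section_gm[!p3$frame_id %in% 5:12]
  expect_gt(min(sub), max(rest))
  p1 <- out$points[out$points$state_index == 1, ]
  expect_lt(mean(p1$cross_section_gm[p1$frame_id %in% 5:12]),
            mean(p1$cross_section_gm[!p1$frame_id %in% 5:12]))
})

test_that("analytic HRS matches the closed single-component limits", {
  h <- beta_hrs_analytic(single_zzz_beta(10))
  expect_equal(h$beta_hrs, 10 * sqrt(6 / 35), tolerance = 1e-12)
  expect_equal(h$depolarization, 5, tolerance = 1e-12)
  expect_equal(h$b2_zzz, 100 / 7, tolerance = 1e-12)
  expect_equal(h$b2_xzz, 100 / 35, tolerance = 1e-12)
  h0 <- beta_hrs_analytic(array(0, c(3, 3, 3)))
  expect_equal(h0$beta_hrs, 0)
  # esu conversion factor applied on the 1e-30 scale
  expect_equal(h$beta_hrs_esu30 / h$beta_hrs, 8.639e-3, tolerance = 1e-3)
})

test_that("analytic HRS equals the Monte-Carlo rotation oracle on random tensors", {
  withr::local_seed(31)
  for (i in 1:6) {
    B <- random_beta()
    ha <- beta_hrs_analytic(B)
    hn <- beta_hrs_numeric(B, n_orientations = 2e5, seed = 100 + i)
    expect_lt(abs(hn$b2_zzz - ha$b2_zzz), 3 * hn$se_b2_zzz)
    expect_lt(abs(hn$b2_xzz - ha$b2_xzz), 3 * hn$se_b2_xzz)
    expect_lt(abs(hn$beta_hrs - ha$beta_hrs), 3 * hn$mc_se)
  }
  # the MC average itself is rotation invariant within error
  B <- random_beta()
  R <- random_rotations(1)[, , 1]
  h1 <- beta_hrs_numeric(B, 2e5, seed = 7)
  h2 <- beta_hrs_numeric(rotate_beta(B, R), 2e5, seed = 8)
  expect_lt(abs(h1$b2_zzz - h2$b2_zzz),
            3 * (h1$se_b2_zzz + h2$se_b2_zzz))
})

test_that("analytic HRS is exactly invariant under proper rotations", {
  withr::local_seed(17)
  B <- random_beta()
  ref <- beta_hrs_analytic(B)$beta_hrs
  for (i in 1:25) {
    R <- random_rotations(1)[, , 1]
    expect_equal(beta_hrs_analytic(rotate_beta(B, R))$beta_hrs, ref,
                 tolerance = 1e-9)
  }
  # rotation preserves determinant +1 (proper rotations only)
  expect_equal(det(random_rotations(1)[, , 1]), 1, tolerance = 1e-12)
})

test_that("hrs_report aggregates per frame and flags missing regimes", {
  withr::local_seed(23)
  frames <- lapply(1:5, function(i) {
    b <- random_beta(100)
    make_frame(i, beta = beta_tensor(b, "static"),
               beta_dyn = beta_tensor(10 * b, "dynamic", wavelength = 810))
  })
  rep <- hrs_report(frames, "both")
  expect_true(rep$static$available && rep$dynamic$available)
  expect_equal(nrow(rep$static$table), 5)
  # componentwise 10x dynamic tensor => exactly 10x the HRS means
  expect_equal(rep$dynamic_static_ratio, 10, tolerance = 1e-12)
  # regime missing -> explicit not-available outcome, no error
  frames_ns <- lapply(1:3, function(i)
    make_frame(i, beta = beta_tensor(random_beta(100), "static")))
  rep2 <- hrs_report(frames_ns, "dynamic")
  expect_false(rep2$dynamic$available)
  expect_match(rep2$dynamic$message, "not available")
  # zero tensors give a zero table
  fz <- list(make_frame(1, beta = beta_tensor(rep(0, 27), "static")))
  repz <- hrs_report(fz, "static")
  expect_equal(repz$static$table$beta_hrs_au, 0)
})

test_that("gel-phase ensembles give the largest HRS response", {
  gel <- hrs_report(generate_phase_frames(builtin_preset("DPPC",
                                                         seed = 19)),
                    "static")
  ld <- hrs_report(generate_phase_frames(builtin_preset("DOPC",
                                                        seed = 19)),
                   "static")
  lo <- hrs_report(generate_phase_frames(builtin_preset("SMCHOL",
                                                        seed = 19)),
                   "static")
  expect_gt(gel$static$mean_esu30, lo$static$mean_esu30)
  expect_gt(lo$static$mean_esu30, ld$static$mean_esu30)
})
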