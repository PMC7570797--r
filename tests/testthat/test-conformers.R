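test_that("torsion angle reproduces planar references and the sign convention", {
  expect_equal(torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, -1, 0)), 180)
  expect_equal(torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, 1, 0)), 0)
  # the signed dihedral is invariant under reversing the atom order and
  # antisymmetric under mirror reflection
  withr::local_seed(5)
  for (i in 1:20) {
    p <- matrix(rnorm(12), 4, 3)
    a <- try(torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ]), silent = TRUE)
    if (inherits(a, "try-error")) next
    b <- torsion_angle(p[4, ], p[3, ], p[2, ], p[1, ])
    expect_equal(b, a, tolerance = 1e-9)
    q <- p; q[, 3] <- -q[, 3]
    m <- torsion_angle(q[1, ], q[2, ], q[3, ], q[4, ])
    d <- abs(probephase:::wrap_angle(a + m))
    expect_lt(min(d, 360 - d), 1e-9)
  }
  expect_error(torsion_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, 1, 0)), "coincident")
  expect_error(torsion_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0),
                             c(2, 1, 0)), "collinear")
})

test_that("torsion angle is invariant under rigid rotations and translations", {
  withr::local_seed(7)
  p <- matrix(c(0, 1, 0, 0, 0, 0, 1, 0, 0, 1.3, 0.7, 0.9), 4, 3,
              byrow = TRUE)
  ref <- torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ])
  for (i in 1:200) {
    R <- random_rotations(1)[, , 1]
    t0 <- rnorm(3, 0, 5)
    q <- t(R %*% t(p)) + matrix(t0, 4, 3, byrow = TRUE)
    expect_equal(torsion_angle(q[1, ], q[2, ], q[3, ], q[4, ]), ref,
                 tolerance = 1e-9)
  }
})

test_that("cis/trans classification is total with the documented thresholds", {
  expect_equal(classify_cis_trans(178, 30), "trans")
  expect_equal(classify_cis_trans(5, 30), "cis")
  expect_equal(classify_cis_trans(95, 30), "gauche")
  expect_equal(classify_cis_trans(-178, 30), "trans")
  expect_equal(classify_cis_trans(c(-10, 160, 80)),
               c("cis", "trans", "gauche"))
  expect_error(classify_cis_trans(10, tolerance = 95), "90")
})

test_that("conformer enumeration yields 8 codes in 6 classes matching the orbit oracle", {
  tab <- enumerate_conformers()
  expect_equal(sum(tab$degeneracy), 8)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$degeneracy[tab$class == "ttt"], 1)
  # asymmetric codes pair with their reversal
  expect_equal(tab$degeneracy[tab$class == "ctt"], 2)
  expect_true(grepl("ttc", tab$members[tab$class == "ctt"]))
  # brute-force orbit oracle for several site counts
  for (k in 1:5) {
    orb <- orbit_count_oracle(k)
    tabk <- enumerate_conformers(k)
    expect_equal(nrow(tabk), length(orb))
    expect_equal(sum(tabk$degeneracy), 2^k)
    expect_equal(sort(tabk$degeneracy), sort(lengths(orb)))
  }
})

test_that("Boltzmann populations normalize, match hand values and are monotone", {
  expect_equal(boltzmann_populations(c(0, 0)), c(0.5, 0.5))
  p <- boltzmann_populations(c(0, 4), temperature = 298)
  # kT = 0.59219 kcal/mol: minor population exp(-4/kT)/(1+exp(-4/kT))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p[2], 0.00117, tolerance = 2e-3)
  # high-T limit proportional to degeneracy
  ph <- boltzmann_populations(c(0, 4), degeneracy = c(1, 3),
                              temperature = 1e9)
  expect_equal(ph, c(0.25, 0.75), tolerance = 1e-6)
  # lowering an energy never decreases its population
  p1 <- boltzmann_populations(c(0, 2, 3))
  p2 <- boltzmann_populations(c(0, 1.5, 3))
  expect_gt(p2[2], p1[2])
  expect_error(boltzmann_populations(numeric(0)), "empty")
  expect_error(boltzmann_populations(c(0, 1), temperature = -1))
})

test_that("dihedral report uses circular statistics and phase presets order the spreads", {
  fr1 <- list(make_frame(1))
  rep1 <- dihedral_report(fr1)
  expect_equal(rep1$circ_spread, rep(0, 7))
  expect_equal(rep1$circ_mean[1], 180)
  expect_equal(rep1$frac_trans[1], 1)
  expect_equal(rep1$frac_cis[7], 1)
  # angles straddling the wrap: circular mean near 180, not 0
  wrap_frames <- lapply(1:2, function(i)
    frame_record(i, i, "DPPC", c(0, 0, 1), 1.2,
                 c(if (i == 1) 175 else -175, rep(180, 6)),
                 list(make_state())))
  ang <- dihedral_report(wrap_frames)
  expect_lt(abs(abs(ang$circ_mean[1]) - 180), 6)
  # liquid-ordered preset wanders dh5 far more than the gel preset
  smc <- generate_phase_frames(builtin_preset("SMCHOL", seed = 4))
  gel <- generate_phase_frames(builtin_preset("DPPC", seed = 4))
  rs <- dihedral_report(smc); rg <- dihedral_report(gel)
  expect_gt(rs$circ_spread[5], rg$circ_spread[5])
  expect_gt(rs$circ_spread[7], rg$circ_spread[7])
  # all-trans presets keep dh1 trans in every frame
  expect_equal(rg$frac_trans[1], 1)
})

test_that("xyz reader and quadruple mapping reproduce known torsions", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("4", "planar zig-zag", "C 0 1 0", "C 0 0 0", "C 1 0 0",
               "C 1 -1 0"), path)
  xyz <- read_xyz(path)
  expect_equal(nrow(xyz), 4)
  ang <- dihedrals_from_xyz(xyz, quadruples = list(1:4))
  expect_equal(unname(ang), 180)
  expect_error(dihedrals_from_xyz(xyz, quadruples = list(2:5)),
               "out of range")
  expect_error(read_xyz(file.path(tempdir(), "nope.xyz")), "not found")
})

test_that("torsion profiles pin the minimum at zero and validate the grid", {
  pr <- torsion_profile("dh1", seq(0, 180, by = 30),
                        c(2, 4, 5.9, 3, 1.2, 0.3, 0.1))
  expect_equal(min(pr$energy), 0)
  expect_error(torsion_profile("dh1", c(0, 0, 30), c(1, 2, 3)),
               "increasing")
})
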