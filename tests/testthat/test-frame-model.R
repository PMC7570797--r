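test_that("frame serialization round-trips losslessly through JSON lines", {
  withr::local_seed(42)
  frames <- generate_phase_frames(builtin_preset("DPPC", seed = 11))
  path <- withr::local_tempfile(fileext = ".jsonl")
  n <- write_frames(frames, path)
  expect_equal(n, 40)
  expect_length(readLines(path), 40)
  back <- read_frames(path)
  expect_length(back, 40)
  expect_equal(vapply(back, `[[`, integer(1), "frame_id"),
               vapply(frames, `[[`, integer(1), "frame_id"))
  for (i in c(1, 17, 40)) {
    a <- frames[[i]]; b <- back[[i]]
    expect_equal(b$phase, a$phase)
    for (j in 1:3) {
      expect_equal(b$states[[j]]$tdm, a$states[[j]]$tdm, tolerance = 1e-12)
      expect_equal(b$states[[j]]$excitation_energy,
                   a$states[[j]]$excitation_energy, tolerance = 1e-12)
      expect_equal(b$states[[j]]$tpa_strength_delta,
                   a$states[[j]]$tpa_strength_delta, tolerance = 1e-12)
    }
    expect_equal(as.numeric(b$beta_dynamic), as.numeric(a$beta_dynamic),
                 tolerance = 1e-12)
    expect_equal(attr(b$beta_dynamic, "wavelength"), 810)
    expect_equal(b$dihedrals, a$dihedrals, tolerance = 1e-12)
  }
})

test_that("empty file and empty record set are handled as degenerate inputs", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  expect_equal(write_frames(list(), path), 0)
  expect_warning(out <- read_frames(path), "empty")
  expect_length(out, 0)
})

test_that("validation rejects every malformed field; strict vs lenient modes", {
  fr <- make_frame()
  # each invariant has a rejecting fixture
  expect_error(frame_record(0, 1, "DPPC", c(0, 0, 1), 1.2,
                            rep(180, 7), list(make_state())), "frame_id")
  expect_error(frame_record(1, -1, "DPPC", c(0, 0, 1), 1.2,
                            rep(180, 7), list(make_state())), "time")
  expect_error(frame_record(1, 1, "DPPC", c(0, 0, 2), 1.2,
                            rep(180, 7), list(make_state())), "unit")
  expect_error(frame_record(1, 1, "DPPC", c(0, 0, 1), 1.2,
                            rep(180, 6), list(make_state())), "7")
  expect_error(frame_record(1, 1, "DPPC", c(0, 0, 1), 1.2,
                            rep(200, 7), list(make_state())), "-180")
  expect_error(frame_record(1, 1, "DPPC", c(0, 0, 1), 1.2,
                            rep(180, 7), list()), "states")
  expect_error(frame_record(1, 1, "DPPC", c(0, 0, 1), 1.2, rep(180, 7),
                            list(make_state(2), make_state(1))), "sorted")
  expect_error(excited_state(1, -3, c(0, 0, 1)), "excitation_energy")
  expect_error(excited_state(1, 3, c(0, 1)), "3 finite")
  expect_error(excited_state(1, 3, c(0, 0, 1), -2), "tpa_strength_delta")
  expect_error(excited_state(0, 3, c(0, 0, 1)), "state_index")
  expect_error(beta_tensor(1:26), "27")
  expect_error(beta_tensor(1:27, "dynamic"), "wavelength")

  # a line with 6 dihedrals: strict errors with the line context,
  # lenient skips with a warning and reports the count
  good <- as.character(jsonlite::toJSON(
    probephase:::frame_to_list(fr), auto_unbox = TRUE, digits = NA))
  bad <- sub("180,180,180,180,180,180,0", "180,180,180,180,180,0", good,
             fixed = TRUE)
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(good, bad), path)
  expect_error(read_frames(path, strict = TRUE), "line 2.*7|7.*line 2")
  expect_warning(out <- read_frames(path, strict = FALSE), "skipped 1")
  expect_length(out, 1)
  expect_equal(attr(out, "skipped"), 1L)
})

test_that("energy conversions are CODATA-consistent and compose bijectively", {
  expect_equal(convert_energy(1239.84, "nm", "eV"), 1, tolerance = 1e-4)
  expect_equal(convert_energy(1, "hartree", "eV"), 27.2114,
               tolerance = 1e-5)
  # round trips and composition to 1e-12 relative
  x <- c(0.8, 3.6, 12.4)
  expect_equal(convert_energy(convert_energy(x, "eV", "nm"), "nm", "eV"),
               x, tolerance = 1e-12)
  via <- convert_energy(convert_energy(x, "eV", "hartree"),
                        "hartree", "nm")
  expect_equal(via, convert_energy(x, "eV", "nm"), tolerance = 1e-12)
  expect_equal(convert_energy(2, "au_omega", "hartree"), 2)
  expect_error(convert_energy(1, "eV", "kJ"))
  expect_error(convert_energy(-3, "eV", "nm"), "positive")
})

test_that("constants round-trip and the phase config supplies the documented defaults", {
  k <- photophysics_constants()
  expect_equal(k$hc_eVnm / k$hc_eVnm, 1)
  expect_equal(k$beta_au_esu, 8.639e-33, tolerance = 1e-3)
  expect_equal(k$gm_per_au_area_time, 1.8968, tolerance = 1e-4)
  cfg <- phase_config()
  expect_equal(cfg$refractive_index[cfg$phase == "DOPC"], 1.378)
  expect_equal(cfg$refractive_index[cfg$phase == "DPPC"], 1.789)
  expect_equal(cfg$refractive_index[cfg$phase == "SMCHOL"], 1.555)
  # YAML override / extension
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("phases:", "  POPC:", "    refractive_index: 1.45",
               "  dopc:", "    refractive_index: 1.40",
               "    temperature: 310"), y)
  cfg2 <- phase_config(y)
  expect_equal(probephase:::phase_refractive_index(cfg2, "POPC"), 1.45)
  expect_equal(cfg2$refractive_index[cfg2$phase == "DOPC"], 1.40)
  expect_error(probephase:::phase_refractive_index(cfg2, "DMPC"), "DMPC")
})
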