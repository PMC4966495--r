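test_that("centroid picking finds intensity-weighted centers", {
  mz <- seq(500, 4000, by = 0.05)
  y <- dnorm(mz, 1000, 0.2)
  pc <- pick_peaks(as_mass_spectrum(tibble::tibble(mz = mz, intensity = y)))
  expect_identical(nrow(pc), 1L)
  expect_equal(pc$mz, 1000, tolerance = 0.01)
  # flat zero spectrum
  flat <- as_mass_spectrum(tibble::tibble(mz = mz, intensity = rep(0, length(mz))))
  expect_identical(nrow(pick_peaks(flat)), 0L)
  # one envelope peak per charge state inside the window
  sp <- make_envelope_spectrum(
    tibble::tibble(mass = fixture_light_plus_1(), intensity = 1,
                   z_min = 15, z_max = 25),
    envelope_config(noise_rel = 0))
  expect_identical(nrow(pick_peaks(sp)), 11L)
  expect_error(as_mass_spectrum(tibble::tibble(mz = numeric(0),
                                               intensity = numeric(0))),
               "Empty")
})

test_that("ppm error is signed, antisymmetric to first order and guarded", {
  expect_equal(ppm_error(23580.0, 23580.0), 0)
  expect_equal(ppm_error(100001, 100000), 10, tolerance = 1e-9)
  expect_equal(ppm_error(23580.0, 23580.2), -8.48, tolerance = 0.01)
  a <- 51630.6; b <- 51631.1
  expect_equal(ppm_error(a, b), -ppm_error(b, a), tolerance = 1e-3)
  expect_error(ppm_error(100, 0), "> 0")
})

test_that("deconvolution round-trips noise-free envelopes", {
  mL <- fixture_light_plus_1()
  mH <- fixture_heavy_g0f_plus_3()
  cfg <- envelope_config(noise_rel = 0)
  dL <- deconvolve(
    make_envelope_spectrum(tibble::tibble(mass = mL, intensity = 1), cfg),
    mass_range = c(mL - 500, mL + 500), charge_range = c(15, 25))
  expect_identical(nrow(dL), 1L)
  expect_equal(dL$neutral_mass, mL, tolerance = 0.5 / mL)
  expect_gte(dL$n_charges, 2L)

  # two-species mixture: both recovered within 1 Da, intensity order kept
  spM <- make_envelope_spectrum(
    tibble::tibble(mass = c(mL, mH), intensity = c(2, 1.2)), cfg)
  dM <- deconvolve(spM, c(22000, 53000), c(10, 50), grid_step = 0.5)
  expect_gte(nrow(dM), 2L)
  hitL <- which.min(abs(dM$neutral_mass - mL))
  hitH <- which.min(abs(dM$neutral_mass - mH))
  expect_lt(abs(dM$neutral_mass[hitL] - mL), 1)
  expect_lt(abs(dM$neutral_mass[hitH] - mH), 1)
  expect_gt(dM$score[hitH], dM$score[hitL] * 0.5) # taller teeth at higher z
})

test_that("a single charge state is never assigned a mass", {
  mL <- fixture_light_plus_1()
  sp1 <- make_envelope_spectrum(
    tibble::tibble(mass = mL, intensity = 1, z_min = 20, z_max = 20),
    envelope_config(noise_rel = 0))
  d1 <- deconvolve(sp1, c(mL - 500, mL + 500), c(15, 25))
  expect_identical(nrow(d1), 0L)
})

test_that("deconvolution is linear in intensity and recovers masses across the working range", {
  mL <- fixture_light_plus_1()
  cfg <- envelope_config(noise_rel = 0)
  sp <- make_envelope_spectrum(tibble::tibble(mass = mL, intensity = 1), cfg)
  sp2 <- as_mass_spectrum(tibble::tibble(mz = sp$mz, intensity = 2 * sp$intensity))
  d1 <- deconvolve(sp, c(mL - 500, mL + 500), c(15, 25))
  d2 <- deconvolve(sp2, c(mL - 500, mL + 500), c(15, 25))
  expect_equal(d2$score, 2 * d1$score, tolerance = 1e-9)
  expect_equal(d2$neutral_mass, d1$neutral_mass, tolerance = 1e-9)

  # round-trip identity over the 20-160 kDa working range
  cases <- list(list(m = 35000, z = c(18, 30)),
                list(m = 90000, z = c(40, 55)),
                list(m = 155000, z = c(48, 60)))
  for (cs in cases) {
    spc <- make_envelope_spectrum(
      tibble::tibble(mass = cs$m, intensity = 1,
                     z_min = cs$z[1], z_max = cs$z[2]), cfg)
    d <- deconvolve(spc, c(cs$m - 800, cs$m + 800), cs$z, grid_step = 0.1)
    expect_equal(d$neutral_mass[1], cs$m, tolerance = 0.5 / cs$m)
  }
})

test_that("mass deltas are explained by the modification table", {
  expect_identical(explain_mass_delta(-17.4), "dehydration")
  expect_identical(explain_mass_delta(162.1), "hexose")
  expect_identical(explain_mass_delta(0), NA_character_)
  expect_error(
    modification_table(tibble::tibble(name = c("a", "b"),
                                      delta = c(10, 11), tolerance = c(1, 1))),
    "Overlapping")
  expect_error(
    modification_table(tibble::tibble(name = "a", delta = 10, tolerance = 0)),
    "> 0")
})
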