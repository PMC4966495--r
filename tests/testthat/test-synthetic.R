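test_that("chromatogram generation is deterministic under a fixed seed", {
  cfg <- hic_batch_config("medium", seed = 42)
  a <- make_hic_chromatogram(cfg, replicate_index = 1)
  b <- make_hic_chromatogram(cfg, replicate_index = 1)
  expect_identical(a$intensity, b$intensity)
  c2 <- make_hic_chromatogram(cfg, replicate_index = 2)
  expect_false(identical(a$intensity, c2$intensity))
  d <- make_hic_chromatogram(hic_batch_config("medium", seed = 43))
  expect_false(identical(a$intensity, d$intensity))
})

test_that("noise-free generation round-trips the configured batch areas", {
  for (batch in c("low", "medium", "high")) {
    cfg <- hic_batch_config(batch, cv_percent = 0, noise_sd = 0)
    truth <- batch_truth(cfg)
    ga <- group_areas(detect_peaks(make_hic_chromatogram(cfg)),
                      default_peak_grouping())
    expect_equal(ga$area_percent, unname(truth$load_percents),
                 tolerance = 0.05 / 100, info = batch)
  }
  # configured percents must sum to ~100
  expect_error(hic_batch_config("custom", load_percents = c(`0` = 50, `8` = 30)),
               "sum to 100")
})

test_that("all-in-one-peak and off-spec configurations behave", {
  cfg <- hic_batch_config("custom",
                          load_percents = c(`0` = 100, `2` = 0, `4` = 0,
                                            `6` = 0, `8` = 0),
                          cv_percent = 0, noise_sd = 0)
  pk <- detect_peaks(make_hic_chromatogram(cfg))
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$apex_time, 2.0, tolerance = 0.01)
})

test_that("generated envelopes stay inside the acquisition window", {
  for (m in c(23580, 51630.6, 102506.3, 147401.5)) {
    sp <- make_envelope_spectrum(tibble::tibble(mass = m, intensity = 1),
                                 envelope_config(noise_rel = 0))
    pc <- pick_peaks(sp)
    expect_true(all(pc$mz >= 500 & pc$mz <= 4000), info = m)
  }
})

test_that("heart-cut spectra deconvolve to the isoform's expected masses", {
  asm <- fixture_assembly()
  cfg <- envelope_config(noise_rel = 0)
  # DAR 8: two masses at the conjugated light and G0F heavy chains
  hc8 <- make_heart_cut_spectrum("8", asm, config = cfg)
  mL <- fixture_light_plus_1(); mH <- fixture_heavy_g0f_plus_3()
  dL <- deconvolve(hc8$spectrum, c(mL - 400, mL + 400), c(15, 25))
  dH <- deconvolve(hc8$spectrum, c(mH - 400, mH + 400), c(30, 45))
  expect_equal(dL$neutral_mass[1], 23580.0, tolerance = 0.5 / 23580)
  expect_equal(dH$neutral_mass[1], 51630.6, tolerance = 0.5 / 51630.6)
  # 6b: three deconvolvable sub-unit masses
  hc6b <- make_heart_cut_spectrum("6b", asm, config = cfg)
  lib <- build_library(asm)
  d <- deconvolve(hc6b$spectrum, range(lib$mass) + c(-2000, 2000),
                  c(10, 60), grid_step = 1, min_support = 5)
  expected <- attr(dissociate("6b", asm), "unique_masses")
  for (m in expected) {
    expect_lt(min(abs(d$neutral_mass - m)), 1, label = paste("mass", m))
  }
  # DAR 0: a single intact species near 147.4 kDa
  hc0 <- make_heart_cut_spectrum("0", asm, config = cfg,
                                 glyco_mix = c(G0F = 1))
  d0 <- deconvolve(hc0$spectrum, c(140000, 155000), c(45, 60), grid_step = 0.5)
  expect_identical(nrow(d0), 1L)
  expect_equal(d0$neutral_mass, intact_mass("0", asm, "G0F"),
               tolerance = 1 / 147000)
  expect_error(make_heart_cut_spectrum("9z", asm), "not in the assembly")
})

test_that("the RP companion trace elutes lighter sub-units first", {
  hc <- make_heart_cut_spectrum("6b", fixture_assembly(),
                                config = envelope_config(noise_rel = 0))
  expect_identical(nrow(dissociate("6b", fixture_assembly())), 3L)
  expect_true(all(hc$rp_trace$time >= 12 & hc$rp_trace$time <= 27))
  expect_gt(max(hc$rp_trace$intensity), 0)
})

test_that("replicate jitter at 0.3% CV is recovered at the right order of magnitude", {
  cfg <- hic_batch_config("medium", cv_percent = 0.3, noise_sd = 0, seed = 19)
  reports <- lapply(1:3, function(r) {
    dar_from_areas(group_areas(detect_peaks(make_hic_chromatogram(cfg, r)),
                               default_peak_grouping()))
  })
  rs <- replicate_stats(reports)
  # per-load RSDs scatter widely at n = 3; the median must sit within a
  # factor of 3 of the injected CV
  expect_gte(median(rs$rsd_percent), 0.1)
  expect_lte(median(rs$rsd_percent), 0.9)
})

test_that("batch datasets carry a complete ground-truth manifest", {
  out <- file.path(tempdir(), "adcdar-batch-test")
  manifest <- make_batch_dataset("high", seed = 5, out_dir = out,
                                 cv_percent = 0, noise_sd = 0, noise_rel = 0)
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_length(manifest$chromatograms, 3L)
  expect_length(manifest$peaks, 8L)
  expect_gte(manifest$total_dar, 5.96)
  expect_lte(manifest$total_dar, 5.97)
  # truth comes from the manifest, pipeline result must agree exactly when
  # noise-free
  chrom <- read_chromatogram_csv(file.path(out, manifest$chromatograms[1]))
  dar <- dar_from_areas(group_areas(detect_peaks(chrom),
                                    default_peak_grouping()))
  expect_equal(round(attr(dar, "total_dar"), 2),
               round(manifest$total_dar, 2))
  expect_error(make_batch_dataset("ultra", seed = 1, out_dir = out),
               "Unknown batch")
  unlink(out, recursive = TRUE)
})

test_that("spectrum and chromatogram CSV round-trips preserve data and metadata", {
  cfg <- hic_batch_config("low", cv_percent = 0, noise_sd = 0)
  chrom <- make_hic_chromatogram(cfg, replicate_index = 2)
  f <- tempfile(fileext = ".csv")
  write_chromatogram_csv(chrom, f)
  back <- read_chromatogram_csv(f)
  expect_equal(back$time, chrom$time)
  expect_equal(back$intensity, chrom$intensity)
  expect_identical(attr(back, "metadata")$batch, "low")
  sp <- make_envelope_spectrum(tibble::tibble(mass = 23580, intensity = 1),
                               envelope_config(noise_rel = 0))
  f2 <- tempfile(fileext = ".csv")
  write_spectrum_csv(sp, f2)
  back2 <- read_spectrum_csv(f2)
  expect_equal(back2$intensity, sp$intensity)
  expect_identical(attr(back2, "mz_range"), c(500, 4000))
  unlink(c(f, f2))
})
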