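gaussian_chrom <- function(apexes, areas, sd = 0.07, run = 10, hz = 20) {
  tm <- seq(0, run, by = 1 / (hz * 60))
  y <- rep(0, length(tm))
  for (i in seq_along(apexes)) y <- y + areas[i] * dnorm(tm, apexes[i], sd)
  as_chromatogram(tibble::tibble(time = tm, intensity = y))
}

test_that("a single noise-free Gaussian integrates to its analytic area", {
  chrom <- gaussian_chrom(5, 2.5)
  pk <- detect_peaks(chrom)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$area, 2.5, tolerance = 0.005)
  expect_equal(pk$relative_area, 100)
  expect_equal(pk$apex_time, 5, tolerance = 0.01)
})

test_that("two baseline-resolved equal Gaussians split 50/50", {
  pk <- detect_peaks(gaussian_chrom(c(3, 7), c(1, 1)))
  expect_identical(nrow(pk), 2L)
  expect_equal(pk$relative_area, c(50, 50), tolerance = 1e-3)
})

test_that("the high-load 8-peak profile is detected and labeled A-H in elution order", {
  cfg <- hic_batch_config("high", cv_percent = 0, noise_sd = 0)
  pk <- detect_peaks(make_hic_chromatogram(cfg))
  expect_identical(pk$label, LETTERS[1:8])
  expect_identical(order(pk$apex_time), 1:8)
  expect_equal(sum(pk$relative_area), 100, tolerance = 0.01)
})

test_that("chromatogram validation rejects malformed input", {
  expect_error(as_chromatogram(data.frame(time = c(1, 1, 2),
                                          intensity = c(0, 1, 0))),
               "strictly increasing")
  expect_error(as_chromatogram(data.frame(time = 1:3,
                                          intensity = c(0, Inf, 0))),
               "finite")
  expect_error(as_chromatogram(data.frame(time = 1, intensity = 1)),
               "at least 3")
})

test_that("grouping sums member peaks and rejects unassigned labels", {
  cfg <- hic_batch_config("high", cv_percent = 0, noise_sd = 0)
  pk <- detect_peaks(make_hic_chromatogram(cfg))
  ga <- group_areas(pk, default_peak_grouping())
  expect_identical(ga$load, c(0L, 2L, 4L, 6L, 8L))
  expect_equal(sum(ga$area_percent), 100, tolerance = 1e-9)
  expect_error(group_areas(pk, c(A = 0)), "B")
  # single peak, single group
  one <- detect_peaks(gaussian_chrom(5, 1))
  expect_equal(group_areas(one, c(A = 4))$area_percent, 100)
})

test_that("DAR computation is the area-weighted drug load", {
  expect_equal(attr(dar_from_areas(c(`0` = 100)), "total_dar"), 0)
  r <- dar_from_areas(c(`0` = 16.73, `2` = 40.71, `4` = 28.56,
                        `6` = 12.54, `8` = 1.50))
  expect_equal(round(attr(r, "total_dar"), 2), 2.83)
  expect_equal(r$dar_contribution, r$area_percent * r$load / 100)
  expect_error(dar_from_areas(c(`0` = -5, `2` = 105)), "non-negative")
  expect_error(dar_from_areas(c(`0` = 10, `2` = 10)), "sum")
})

test_that("total DAR is invariant to overall area scaling and bounded by the load range", {
  cfg <- hic_batch_config("medium", cv_percent = 0, noise_sd = 0)
  chrom <- make_hic_chromatogram(cfg)
  scaled <- as_chromatogram(tibble::tibble(time = chrom$time,
                                           intensity = 3.7 * chrom$intensity))
  d1 <- dar_from_areas(group_areas(detect_peaks(chrom), default_peak_grouping()))
  d2 <- dar_from_areas(group_areas(detect_peaks(scaled), default_peak_grouping()))
  expect_equal(attr(d1, "total_dar"), attr(d2, "total_dar"), tolerance = 1e-9)
  # any valid percent vector stays within [0, 8]
  set.seed(11)
  for (i in 1:25) {
    p <- runif(5); p <- 100 * p / sum(p)
    total <- attr(dar_from_areas(setNames(p, c(0, 2, 4, 6, 8))), "total_dar")
    expect_gte(total, 0)
    expect_lte(total, 8)
  }
})

test_that("replicate statistics compute sample RSDs and flag single replicates", {
  mk <- function(p8) dar_from_areas(c(`0` = 20, `2` = 30, `4` = 30,
                                      `6` = 20 - p8, `8` = p8))
  same <- replicate_stats(list(mk(5), mk(5), mk(5)))
  expect_equal(same$rsd_percent, rep(0, 5))
  expect_equal(attr(same, "total_rsd"), 0)
  # hand-computed: mean 2.83, sd 0.01 -> RSD 0.3534%
  fake <- lapply(c(2.82, 2.83, 2.84), function(t) {
    r <- dar_from_areas(c(`0` = 100))
    attr(r, "total_dar") <- t
    r
  })
  rs <- replicate_stats(fake)
  expect_equal(attr(rs, "total_dar"), 2.83)
  expect_equal(attr(rs, "total_rsd"), 100 * sd(c(2.82, 2.83, 2.84)) / 2.83,
               tolerance = 1e-9)
  expect_warning(single <- replicate_stats(list(mk(5))), "Single replicate")
  expect_true(all(is.na(single$rsd_percent)))
  expect_error(replicate_stats(list(mk(5), dar_from_areas(c(`0` = 100)))),
               "same load grouping")
})

test_that("heart-cut volume follows window x flow and respects the time span", {
  chrom <- gaussian_chrom(5, 1)
  hc <- extract_heart_cut(chrom, 5.0, 5.2, flow_rate = 0.5)
  expect_equal(hc$volume_ml, 0.1, tolerance = 1e-12)
  zero <- extract_heart_cut(chrom, 5.0, 5.0, flow_rate = 0.5)
  expect_identical(zero$volume_ml, 0)
  expect_identical(nrow(zero$composition), 0L)
  expect_error(extract_heart_cut(chrom, 9.9, 10.3), "outside")
})

test_that("a post-apex cut enriches the later-eluting species", {
  profiles <- tibble::tibble(species = c("early", "late"),
                             apex_time = c(5.0, 5.4), sd = 0.2,
                             area = c(1, 1))
  chrom <- gaussian_chrom(c(5.0, 5.4), c(1, 1), sd = 0.2)
  apex_cut <- extract_heart_cut(chrom, 4.9, 5.1, species_profiles = profiles)
  post_cut <- extract_heart_cut(chrom, 5.1, 5.3, species_profiles = profiles)
  late_share <- function(hc) hc$composition$share[hc$composition$species == "late"]
  expect_gt(late_share(post_cut), late_share(apex_cut))
  # purge delay trims the composition window
  trimmed <- extract_heart_cut(chrom, 4.9, 5.1, purge_delay = 0.05,
                               species_profiles = profiles)
  expect_equal(trimmed$volume_ml, apex_cut$volume_ml)
  expect_false(isTRUE(all.equal(trimmed$composition$share,
                                apex_cut$composition$share)))
})
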