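test_that("the signature library has one entry per isoform with glycoform variants", {
  lib <- build_library(fixture_assembly())
  expect_identical(length(unique(lib$isoform_label)), 9L)
  ref <- lib[lib$is_reference, ]
  # reported second-dimension peak counts
  expect_identical(sum(ref$isoform_label == "8"), 2L)
  expect_identical(sum(ref$isoform_label == "6b"), 3L)
  # heavy-bearing groups carry both glycoform variants
  heavy8 <- lib[lib$isoform_label == "8" & !is.na(lib$glycoform), ]
  expect_setequal(heavy8$glycoform, c("G0F", "G1F"))
})

test_that("each isoform's own signature is uniquely assigned (self-consistency)", {
  asm <- fixture_assembly()
  lib <- build_library(asm)
  for (l in unique(lib$isoform_label)) {
    obs <- attr(dissociate(l, asm), "unique_masses")
    res <- match_observed(obs, lib)
    expect_true(res$unique, info = l)
    expect_identical(res$best, l)
  }
})

test_that("the dissociated sub-unit pair 23,580.0 / 51,630.6 identifies DAR 8 uniquely", {
  lib <- build_library(fixture_assembly())
  res <- match_observed(c(23580.0, 51630.6), lib)
  expect_true(res$unique)
  expect_identical(res$best, "8")
})

test_that("the light+1 mass alone is shared and therefore non-unique", {
  lib <- build_library(fixture_assembly())
  res <- match_observed(fixture_light_plus_1(), lib)
  expect_false(res$unique)
  # every drug-loaded isoform whose signature contains light+1 explains it
  sharers <- res$candidates$isoform_label[res$candidates$n_unexplained == 0]
  expect_setequal(sharers, c("2a", "4a", "4b", "6a", "6b", "8"))
  expect_error(match_observed(numeric(0), lib), "No observed masses")
})

test_that("unique assignments tolerate 5 ppm perturbation at 10 ppm tolerance", {
  asm <- fixture_assembly()
  lib <- build_library(asm)
  for (l in c("8", "6b", "4a", "2b")) {
    obs <- attr(dissociate(l, asm), "unique_masses")
    for (shift in c(-5e-6, 5e-6)) {
      res <- match_observed(obs * (1 + shift), lib)
      expect_true(res$unique, info = paste(l, shift))
      expect_identical(res$best, l)
    }
  }
})

test_that("dropping any expected mass of a multi-mass isoform demotes uniqueness", {
  asm <- fixture_assembly()
  lib <- build_library(asm)
  obs <- sort(attr(dissociate("6b", asm), "unique_masses"))
  for (drop in seq_along(obs)) {
    res <- match_observed(obs[-drop], lib)
    # 6b can no longer be the unique complete explanation (though a smaller
    # isoform may become one, e.g. dropping the 74.5 kDa mass leaves the
    # DAR 8 pair)
    expect_false(identical(res$best, "6b"), info = paste("dropped", drop))
    cand6b <- res$candidates[res$candidates$isoform_label == "6b", ]
    expect_gt(cand6b$n_unobserved, 0)
  }
})

test_that("a dehydration satellite co-explains an observed mass without breaking assignment", {
  asm <- fixture_assembly()
  lib <- build_library(asm)
  obs <- attr(dissociate("4a", asm), "unique_masses")
  hh <- max(obs)
  res <- match_observed(c(obs, hh - 18.02), lib)
  expect_true(res$unique)
  expect_identical(res$best, "4a")
  matches <- res$candidates$matches[[which(res$candidates$isoform_label == "4a")]]
  expect_true("dehydration" %in% matches$modification)
})

test_that("uniqueness analysis finds no identical pairs and flags subset confounds", {
  lib <- build_library(fixture_assembly())
  rep <- uniqueness_analysis(lib)
  expect_false(any(rep$relation == "identical"))
  # the DAR 8 pair is contained in 6b's triple (co-elution confound)
  expect_true(any(rep$isoform_a == "8" & rep$isoform_b == "6b" &
                    rep$relation == "subset"))
  # single-isoform library has nothing to report
  solo <- lib[lib$isoform_label == "8", ]
  class(solo) <- class(lib)
  expect_identical(nrow(uniqueness_analysis(solo)), 0L)
})
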