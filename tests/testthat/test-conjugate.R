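test_that("IgG1 enumeration yields 9 classes with the expected multiplicities", {
  iso <- enumerate_isoforms(fixture_assembly())
  expect_identical(nrow(iso), 9L)
  expect_identical(iso$label,
                   c("0", "2a", "2b", "4a", "4b", "4c", "6a", "6b", "8"))
  per_dar <- table(iso$dar)
  expect_identical(as.integer(per_dar[c("0", "2", "4", "6", "8")]),
                   c(1L, 2L, 3L, 2L, 1L))
  # every reduction state appears in exactly one class
  expect_identical(sum(iso$n_members), 16L)
  # label semantics: suffixes ordered by number of reduced LC-HC bonds
  expect_identical(iso$n_lchc_reduced[iso$label == "4a"], 2L)
  expect_identical(iso$n_lchc_reduced[iso$label == "4c"], 0L)
  expect_identical(iso$n_lchc_reduced[iso$label == "6a"], 2L)
  expect_identical(iso$n_lchc_reduced[iso$label == "6b"], 1L)
  # 6b representative: one LC-HC plus both hinge bonds
  rep6b <- iso$representative[iso$label == "6b"][[1]]
  expect_identical(sum(grepl("hinge", rep6b)), 2L)
})

test_that("enumeration agrees with a brute-force orbit partition on several topologies", {
  assemblies <- list(igg1 = fixture_assembly(),
                     single = single_bond_assembly(),
                     none = no_bond_assembly(),
                     six = six_bond_assembly())
  for (nm in names(assemblies)) {
    asm <- assemblies[[nm]]
    iso <- enumerate_isoforms(asm)
    oracle <- oracle_partition(asm)
    expect_identical(nrow(iso), length(oracle), info = nm)
    expect_identical(sort(iso$n_members),
                     sort(vapply(oracle, length, integer(1))), info = nm)
    expect_identical(sum(iso$n_members), as.integer(2^nrow(asm$bonds)),
                     info = nm)
  }
  # trivial cases pinned explicitly
  expect_identical(nrow(enumerate_isoforms(no_bond_assembly())), 1L)
  expect_identical(enumerate_isoforms(no_bond_assembly())$dar, 0L)
  expect_identical(nrow(enumerate_isoforms(single_bond_assembly())), 2L)
  expect_identical(sort(enumerate_isoforms(single_bond_assembly())$dar),
                   c(0L, 2L))
})

test_that("invalid symmetry is rejected", {
  expect_error(
    adc_assembly(
      chains = list(L1 = chain_spec("light", 100), H1 = chain_spec("heavy", 200)),
      bonds = tibble::tibble(id = "b1", chain_a = "L1", chain_b = "H1",
                             site_class = "LC-HC"),
      symmetry = list(chains = character(0), bonds = c(b1 = "b2")),
      drug = drug_linker(mass = 376.46)
    ),
    "bond set"
  )
})

test_that("dissociation signatures match the observed second-dimension peak counts", {
  asm <- fixture_assembly()
  expect_length(attr(dissociate("8", asm), "unique_masses"), 2L)
  expect_length(attr(dissociate("6b", asm), "unique_masses"), 3L)
  sig0 <- dissociate("0", asm)
  expect_identical(nrow(sig0), 1L)
  expect_identical(sig0$drug_count, 0L)
  # 6b sub-units: light+1, heavy+3, (heavy+light)+2
  m6b <- sort(attr(dissociate("6b", asm), "unique_masses"))
  expect_equal(round(m6b, 1), c(23580.0, 51630.6, 74455.7))
})

test_that("mass conservation and drug bookkeeping hold for every isoform and glycoform", {
  asm <- fixture_assembly()
  iso <- enumerate_isoforms(asm)
  for (l in iso$label) {
    for (g in c("G0F", "G1F")) {
      sig <- dissociate(l, asm, glycoform = g)
      expect_lt(abs(sum(sig$mass * sig$n_copies) - intact_mass(l, asm, g)),
                1e-6)
      expect_identical(sum(sig$drug_count * sig$n_copies),
                       iso$dar[iso$label == l])
    }
  }
})

test_that("the 9 fixture signatures are pairwise distinct and intact mass grows with DAR", {
  asm <- fixture_assembly()
  iso <- enumerate_isoforms(asm)
  sets <- lapply(iso$label, function(l) {
    sort(round(attr(dissociate(l, asm), "unique_masses"), 1))
  })
  keys <- vapply(sets, paste, character(1), collapse = "|")
  expect_identical(anyDuplicated(keys), 0L)
  intact <- vapply(iso$label, intact_mass, numeric(1),
                   assembly = asm, glycoform = "G0F")
  expect_true(all(diff(intact[order(iso$dar, intact)]) >= 0))
  # strictly increasing across DAR levels (drug mass > 2 x decrement)
  per_dar <- tapply(intact, iso$dar, unique)
  expect_true(all(diff(vapply(per_dar, `[[`, numeric(1), 1)) > 0))
})

test_that("sub-unit masses reproduce the reported conjugated chain masses", {
  asm <- fixture_assembly()
  expect_equal(round(fixture_light_plus_1(), 1), 23580.0)
  expect_equal(round(fixture_heavy_g0f_plus_3(), 1), 51630.6)
  # identity case: no drugs, no internal bonds
  expect_identical(subunit_mass(asm, "L1"), 23203.54)
  # algebra of the mass model
  expect_equal(intact_mass("8", asm, "G0F"),
               intact_mass("0", asm, "G0F") + 8 * 376.46 + 4 * 2.016,
               tolerance = 1e-12)
  expect_error(subunit_mass(asm, "L1", glycoform = "G0F"), "no heavy chain")
  expect_error(subunit_mass(asm, "H1", glycoform = "G9"), "Unknown glycoform")
})

test_that("the bundled conjugate configuration reproduces the built-in fixture", {
  path <- system.file("extdata", "conjugate_igg1.yaml", package = "adcdar")
  asm <- read_conjugate_config(path)
  expect_identical(nrow(enumerate_isoforms(asm)), 9L)
  expect_equal(round(subunit_mass(asm, "L1", 1), 1), 23580.0)
  expect_equal(round(subunit_mass(asm, "H1", 3, glycoform = "G0F"), 1),
               51630.6)
  expect_error(read_conjugate_config("/nonexistent/conjugate.yaml"),
               "not found")
})

test_that("the signature table exports one row per sub-unit per glycoform", {
  tab <- signature_table(fixture_assembly())
  expect_true(all(c("isoform_label", "dar", "mass_da") %in% names(tab)))
  # 9 isoforms x 2 glycoforms, at least one sub-unit each
  expect_identical(length(unique(tab$isoform_label)), 9L)
  expect_setequal(unique(tab$glycoform[!is.na(tab$glycoform)]),
                  c("G0F", "G1F"))
})
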