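# Shared fixtures for the test suite. Everything is built in code; no data
# files are read from disk except those the tests themselves write to
# tempdir().

fixture_assembly <- function() fixture_igg1()

# model sub-unit masses of the fully conjugated species
fixture_light_plus_1 <- function() {
  subunit_mass(fixture_assembly(), "L1", drug_count = 1)
}
fixture_heavy_g0f_plus_3 <- function() {
  subunit_mass(fixture_assembly(), "H1", drug_count = 3, glycoform = "G0F")
}

# a minimal assembly: two chains, one LC-HC bond, trivial symmetry
single_bond_assembly <- function() {
  adc_assembly(
    chains = list(L1 = chain_spec("light", 23203.54),
                  H1 = chain_spec("heavy", 50501.22)),
    bonds = tibble::tibble(id = "L1-H1", chain_a = "L1", chain_b = "H1",
                           site_class = "LC-HC"),
    symmetry = list(chains = character(0), bonds = character(0)),
    drug = drug_linker(mass = 376.46)
  )
}

# an assembly with no inter-chain bonds at all
no_bond_assembly <- function() {
  adc_assembly(
    chains = list(L1 = chain_spec("light", 23203.54),
                  H1 = chain_spec("heavy", 50501.22)),
    bonds = tibble::tibble(id = character(0), chain_a = character(0),
                           chain_b = character(0), site_class = character(0)),
    symmetry = list(chains = character(0), bonds = character(0)),
    drug = drug_linker(mass = 376.46)
  )
}

# a 6-bond topology: the IgG1 plus a third interchangeable hinge pair
six_bond_assembly <- function() {
  adc_assembly(
    chains = list(L1 = chain_spec("light", 23203.54),
                  L2 = chain_spec("light", 23203.54),
                  H1 = chain_spec("heavy", 50501.22),
                  H2 = chain_spec("heavy", 50501.22)),
    bonds = tibble::tibble(
      id = c("L1-H1", "L2-H2", "hinge-1", "hinge-2", "hinge-3", "hinge-4"),
      chain_a = c("L1", "L2", "H1", "H1", "H1", "H1"),
      chain_b = c("H1", "H2", "H2", "H2", "H2", "H2"),
      site_class = c("LC-HC", "LC-HC", "hinge", "hinge", "hinge", "hinge")
    ),
    symmetry = list(generators = list(
      list(chains = c(L1 = "L2", L2 = "L1", H1 = "H2", H2 = "H1"),
           bonds = c("L1-H1" = "L2-H2", "L2-H2" = "L1-H1")),
      list(chains = character(0),
           bonds = c("hinge-1" = "hinge-2", "hinge-2" = "hinge-1")),
      list(chains = character(0),
           bonds = c("hinge-3" = "hinge-4", "hinge-4" = "hinge-3"))
    )),
    drug = drug_linker(mass = 376.46)
  )
}

# Independent brute-force partition of reduction states: BFS closure of each
# subset under repeated application of the symmetry generators. Used as the
# oracle against enumerate_isoforms(), which canonizes via the closed group.
oracle_partition <- function(assembly) {
  ids <- assembly$bonds$id
  gens <- lapply(
    if (!is.null(assembly$symmetry$generators)) assembly$symmetry$generators
    else list(assembly$symmetry),
    function(s) {
      full <- stats::setNames(ids, ids)
      full[names(s$bonds)] <- unname(s$bonds)
      full
    }
  )
  n <- length(ids)
  all_subsets <- lapply(0:(2^max(n, 0) - 1), function(mask) {
    if (n == 0) character(0) else ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
  })
  key <- function(s) paste(sort(s), collapse = "|")
  seen <- character(0)
  classes <- list()
  for (s in all_subsets) {
    if (key(s) %in% seen) next
    frontier <- list(s)
    orbit <- stats::setNames(list(s), key(s))
    while (length(frontier) > 0) {
      nxt <- list()
      for (x in frontier) {
        for (g in gens) {
          y <- unname(g[x])
          if (!key(y) %in% names(orbit)) {
            orbit[[key(y)]] <- y
            nxt[[length(nxt) + 1]] <- y
          }
        }
      }
      frontier <- nxt
    }
    seen <- c(seen, names(orbit))
    classes[[length(classes) + 1]] <- orbit
  }
  classes
}
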