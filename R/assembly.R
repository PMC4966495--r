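# Conjugate assembly model: chains, inter-chain disulfides, drug linker.
#
# A cysteine-conjugated ADC is modelled as four chain instances (L1, L2, H1,
# H2 for an IgG1) connected by inter-chain disulfide bonds. Chain base masses
# are defined in the fully reduced state (all inter-chain cysteines as free
# thiols, intra-chain disulfides and constant modifications folded in); each
# intact inter-chain bond then subtracts one disulfide decrement (2 H), which
# keeps all downstream mass arithmetic additive and conservation exact.

#' Describe a maleimide drug linker
#'
#' @param formula Optional molecular formula string for the drug-linker.
#' @param mass Average mass in Da. If omitted, computed from `formula`.
#' @param attachment Conjugation chemistry tag. Thiol-maleimide Michael
#'   addition adds the full drug mass to the chain (no leaving group).
#' @return A `drug_linker` object.
#' @examples
#' drug_linker("C23H24N2O3", mass = 376.46)
#' @export
drug_linker <- function(formula = NULL, mass = NULL,
                        attachment = "thiol-maleimide") {
  if (is.null(mass)) {
    if (is.null(formula)) abort("Provide a formula or a mass for the drug linker")
    mass <- average_mass(formula)
  }
  if (!is.numeric(mass) || mass <= 0) abort("Drug average mass must be > 0")
  structure(
    list(formula = formula, average_mass = as.numeric(mass),
         attachment = attachment),
    class = "drug_linker"
  )
}

#' @export
print.drug_linker <- function(x, ...) {
  cat("<drug_linker> ", x$attachment, ", ",
      format(x$average_mass, nsmall = 2), " Da",
      if (!is.null(x$formula)) paste0(" (", x$formula, ")"), "\n", sep = "")
  invisible(x)
}

#' Describe an antibody chain
#'
#' @param role `"light"` or `"heavy"`.
#' @param reduced_average_mass Average mass (Da) of the chain with all
#'   inter-chain cysteines as free thiols.
#' @param glycoforms Tibble with columns `name`, `delta` (Da) of N-glycoforms
#'   applicable to this chain. Light chains must have none.
#' @return A `chain_spec` object.
#' @export
chain_spec <- function(role = c("light", "heavy"), reduced_average_mass,
                       glycoforms = NULL) {
  role <- match.arg(role)
  if (!is.numeric(reduced_average_mass) || reduced_average_mass <= 0) {
    abort("reduced_average_mass must be > 0")
  }
  if (is.null(glycoforms)) {
    glycoforms <- tibble(name = character(0), delta = numeric(0))
  }
  glycoforms <- as_tibble(glycoforms)
  if (role == "light" && nrow(glycoforms) > 0) {
    abort("Light chains carry no glycoforms")
  }
  structure(
    list(role = role, reduced_average_mass = as.numeric(reduced_average_mass),
         glycoforms = glycoforms),
    class = "chain_spec"
  )
}

#' Build an ADC assembly
#'
#' An assembly is the set of chain instances, the inter-chain disulfide bonds
#' connecting them, the 2-fold molecular symmetry that identifies equivalent
#' reduction states, and the drug-linker chemistry.
#'
#' @param chains Named list of [chain_spec()] objects; names are chain
#'   instance ids (e.g. `L1`, `L2`, `H1`, `H2`).
#' @param bonds Tibble with columns `id`, `chain_a`, `chain_b`, `site_class`
#'   (`"LC-HC"` or `"hinge"`). Each bond connects two different chain
#'   instances; its reduction creates exactly two conjugation sites.
#' @param symmetry Either a single generator (named list with character
#'   vectors `chains` and `bonds`, each a named permutation `old = new`) or
#'   a list of such generators under a `generators` element. Each generator
#'   must be an involution mapping the bond set onto itself; reduction
#'   states are collapsed under the group the generators generate. For an
#'   IgG1 the group is generated by the 2-fold arm swap and the exchange of
#'   the two (structurally interchangeable) hinge bonds.
#' @param drug A [drug_linker()].
#' @param disulfide_decrement Mass (Da) subtracted per intact inter-chain
#'   bond relative to the fully reduced chains (loss of 2 H = 2.016 Da).
#' @return An `adc_assembly` object.
#' @seealso [igg1_assembly()] for the standard 4-bond IgG1 topology.
#' @export
adc_assembly <- function(chains, bonds, symmetry, drug,
                         disulfide_decrement = 2.016) {
  bonds <- as_tibble(bonds)
  stopifnot(is.list(chains), !is.null(names(chains)))
  needed <- c("id", "chain_a", "chain_b", "site_class")
  if (!all(needed %in% names(bonds))) {
    abort(paste0("bonds needs columns: ", paste(needed, collapse = ", ")))
  }
  if (any(bonds$chain_a == bonds$chain_b)) {
    abort("A disulfide bond must connect two different chain instances")
  }
  missing_chain <- setdiff(c(bonds$chain_a, bonds$chain_b), names(chains))
  if (length(missing_chain) > 0) {
    abort(paste0("Bond endpoint on unknown chain: ",
                 paste(missing_chain, collapse = ", ")))
  }
  if (anyDuplicated(bonds$id)) abort("Bond ids must be unique")
  if (!inherits(drug, "drug_linker")) drug <- do.call(drug_linker, drug)
  asm <- structure(
    list(chains = chains, bonds = bonds, symmetry = symmetry, drug = drug,
         disulfide_decrement = as.numeric(disulfide_decrement)),
    class = "adc_assembly"
  )
  .check_symmetry(asm)
  asm
}

# Normalize the symmetry spec to a list of generators.
.symmetry_generators <- function(symmetry) {
  if (!is.null(symmetry$generators)) symmetry$generators else list(symmetry)
}

# Every generator must be an involution on bond ids mapping the bond set
# onto itself and consistent with its chain permutation.
.check_symmetry <- function(asm) {
  for (sym in .symmetry_generators(asm$symmetry)) {
    bond_map <- .complete_permutation(sym$bonds, asm$bonds$id)
    chain_map <- .complete_permutation(sym$chains, names(asm$chains))
    if (!setequal(names(bond_map), asm$bonds$id) ||
        !setequal(unname(bond_map), asm$bonds$id)) {
      abort("Symmetry does not map the bond set onto itself")
    }
    # involution: applying twice is the identity
    if (!identical(unname(bond_map[bond_map[asm$bonds$id]]), asm$bonds$id)) {
      abort("Bond symmetry is not an involution")
    }
    if (!identical(unname(chain_map[chain_map[names(asm$chains)]]),
                   names(asm$chains))) {
      abort("Chain symmetry is not an involution")
    }
    # consistency: the image of a bond connects the images of its endpoints
    for (i in seq_len(nrow(asm$bonds))) {
      b <- asm$bonds[i, ]
      img <- asm$bonds[asm$bonds$id == bond_map[[b$id]], ]
      if (!setequal(c(chain_map[[b$chain_a]], chain_map[[b$chain_b]]),
                    c(img$chain_a, img$chain_b))) {
        abort(paste0("Symmetry image of bond ", b$id,
                     " does not connect the image chains"))
      }
    }
  }
  invisible(asm)
}

# Closure of the bond permutation group generated by the symmetry
# generators; returns a list of total permutations (named char vectors).
.bond_group <- function(asm, max_order = 1024L) {
  ids <- asm$bonds$id
  identity_map <- setNames(ids, ids)
  if (length(ids) == 0L) return(list(identity_map))
  gens <- lapply(.symmetry_generators(asm$symmetry),
                 function(s) .complete_permutation(s$bonds, ids))
  key <- function(p) paste(p[ids], collapse = "|")
  group <- list(identity_map)
  names(group) <- key(identity_map)
  frontier <- group
  while (length(frontier) > 0) {
    new_elems <- list()
    for (p in frontier) {
      for (g in gens) {
        q <- setNames(unname(g[p[ids]]), ids)
        k <- key(q)
        if (is.null(group[[k]]) && is.null(new_elems[[k]])) {
          new_elems[[k]] <- q
        }
      }
    }
    group <- c(group, new_elems)
    frontier <- new_elems
    if (length(group) > max_order) {
      abort("Symmetry group closure exceeds the supported order")
    }
  }
  unname(group)
}

# Fill in fixed points so a partial permutation spec becomes total.
.complete_permutation <- function(map, ids) {
  map <- map %||% character(0)
  full <- setNames(ids, ids)
  full[names(map)] <- unname(map)
  full
}

#' Standard IgG1 assembly (2 light + 2 heavy chains, 4 inter-chain bonds)
#'
#' Builds the canonical IgG1 inter-chain disulfide topology: two light-heavy
#' bonds (L1-H1, L2-H2) and two heavy-heavy hinge bonds (H1-H2), with the
#' 2-fold symmetry swapping (L1,H1) with (L2,H2) and the two hinge bonds.
#'
#' @param light_mass,heavy_mass Reduced average chain masses in Da.
#' @param glycoforms Tibble (`name`, `delta`) of heavy-chain glycoforms.
#' @param drug A [drug_linker()] (or list coercible to one).
#' @param disulfide_decrement Da per intact bond; default 2.016.
#' @return An `adc_assembly`.
#' @examples
#' asm <- igg1_assembly(23203.54, 50501.22,
#'   glycoforms = tibble::tibble(name = c("G0F", "G1F"), delta = c(0, 162.14)),
#'   drug = drug_linker("C23H24N2O3", mass = 376.46))
#' @export
igg1_assembly <- function(light_mass, heavy_mass,
                          glycoforms = tibble(name = "G0F", delta = 0),
                          drug = drug_linker("C23H24N2O3", mass = 376.46),
                          disulfide_decrement = 2.016) {
  light <- chain_spec("light", light_mass)
  heavy <- chain_spec("heavy", heavy_mass, glycoforms)
  adc_assembly(
    chains = list(L1 = light, L2 = light, H1 = heavy, H2 = heavy),
    bonds = tibble(
      id = c("L1-H1", "L2-H2", "hinge-1", "hinge-2"),
      chain_a = c("L1", "L2", "H1", "H1"),
      chain_b = c("H1", "H2", "H2", "H2"),
      site_class = c("LC-HC", "LC-HC", "hinge", "hinge")
    ),
    symmetry = list(generators = list(
      # 2-fold molecular symmetry swapping the two half-antibody arms
      list(chains = c(L1 = "L2", L2 = "L1", H1 = "H2", H2 = "H1"),
           bonds = c("L1-H1" = "L2-H2", "L2-H2" = "L1-H1",
                     "hinge-1" = "hinge-2", "hinge-2" = "hinge-1")),
      # the two hinge bonds connect the same chain pair and are
      # interchangeable: one hinge reduced is a single species
      list(chains = character(0),
           bonds = c("hinge-1" = "hinge-2", "hinge-2" = "hinge-1"))
    )),
    drug = drug,
    disulfide_decrement = disulfide_decrement
  )
}

#' @export
print.adc_assembly <- function(x, ...) {
  cat("<adc_assembly> ", length(x$chains), " chains, ",
      nrow(x$bonds), " inter-chain disulfide bonds\n", sep = "")
  print(x$bonds)
  invisible(x)
}

#' Reference IgG1 conjugate used throughout the package
#'
#' Chain masses are back-derived so that the light chain plus one drug is
#' 23,580.0 Da and the G0F heavy chain plus three drugs is 51,630.6 Da, with
#' a 376.46 Da maleimide drug mimic, G1F at +162.14 Da and a 2.016 Da
#' decrement per intact disulfide. These are synthetic reference values (the
#' underlying mAb sequence is not public), chosen to reproduce the reported
#' dissociated sub-unit masses.
#'
#' @return An `adc_assembly`.
#' @examples
#' fixture_igg1()
#' @export
fixture_igg1 <- function() {
  igg1_assembly(
    light_mass = 23203.54,
    heavy_mass = 50501.22,
    glycoforms = tibble(name = c("G0F", "G1F"), delta = c(0, 162.14)),
    drug = drug_linker("C23H24N2O3", mass = 376.46),
    disulfide_decrement = 2.016
  )
}

#' Read a conjugate configuration file
#'
#' Loads an assembly from a YAML (or JSON) configuration with fields
#' `chains`, `glycoforms`, `drug`, `bonds`, `symmetry` and
#' `disulfide_decrement`. A bundled default encoding the reference IgG1 is at
#' `system.file("extdata", "conjugate_igg1.yaml", package = "adcdar")`.
#'
#' @param path Path to the configuration file.
#' @return An `adc_assembly`.
#' @export
read_conjugate_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Conjugate config not found: ", path))
  cfg <- yaml::read_yaml(path)
  glyco <- if (!is.null(cfg$glycoforms)) {
    dplyr::bind_rows(lapply(cfg$glycoforms, as_tibble))
  } else {
    NULL
  }
  chains <- lapply(cfg$chains, function(ch) {
    chain_spec(ch$role, ch$reduced_average_mass,
               glycoforms = if (identical(ch$role, "heavy")) glyco)
  })
  bonds <- dplyr::bind_rows(lapply(cfg$bonds, as_tibble))
  drug <- drug_linker(formula = cfg$drug$formula, mass = cfg$drug$average_mass)
  sym <- if (!is.null(cfg$symmetry$generators)) {
    list(generators = lapply(cfg$symmetry$generators, function(g) {
      list(chains = unlist(g$chains), bonds = unlist(g$bonds))
    }))
  } else {
    list(chains = unlist(cfg$symmetry$chains),
         bonds = unlist(cfg$symmetry$bonds))
  }
  adc_assembly(chains, bonds, sym, drug,
               disulfide_decrement = cfg$disulfide_decrement %||% 2.016)
}
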