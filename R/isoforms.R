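# Positional-isomer enumeration and dissociation signatures.
#
# Partial reduction of the inter-chain disulfides followed by maleimide
# conjugation caps every freed cysteine with one drug, so a reduction state
# (a subset of the inter-chain bonds) carries 2 drugs per reduced bond.
# Reduction states that map onto each other under the molecular 2-fold
# symmetry are chemically indistinguishable and are collapsed into one
# positional isoform class. Under denaturing reversed-phase conditions the
# conjugate falls apart into its covalent sub-units: the connected components
# of the chain graph under the *intact* bonds.

#' Enumerate positional isoform classes of an assembly
#'
#' Every subset of the inter-chain disulfide bonds is a reduction state;
#' states equivalent under the assembly symmetry form one isoform class.
#' For the standard IgG1 topology (4 bonds, 2-fold symmetry) this yields 9
#' classes with drug loads 0, 2, 4, 6, 8 and multiplicities 1/2/3/2/1.
#'
#' Labels follow the field's convention: the drug count, with suffixes
#' a, b, c assigned within a drug load by decreasing number of reduced
#' light-heavy bonds (so 4a = both LC-HC reduced, 4c = both hinge reduced,
#' 6b = one LC-HC + both hinge).
#'
#' @param assembly An [adc_assembly()].
#' @return A tibble of class `isoform_classes` with columns `label`, `dar`,
#'   `n_lchc_reduced`, `n_members`, `representative` and `members`
#'   (list-columns of bond-id character vectors), sorted by (dar, label).
#' @examples
#' enumerate_isoforms(fixture_igg1())
#' @export
enumerate_isoforms <- function(assembly) {
  stopifnot(inherits(assembly, "adc_assembly"))
  ids <- assembly$bonds$id
  n <- length(ids)
  group <- .bond_group(assembly)
  site <- setNames(assembly$bonds$site_class, ids)

  subset_key <- function(s) paste(sort(s), collapse = "|")
  subsets <- lapply(0:(2^n - 1), function(mask) ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  if (n == 0L) subsets <- list(character(0))
  canon <- vapply(subsets, function(s) {
    min(vapply(group, function(p) subset_key(unname(p[s])), character(1)))
  }, character(1))

  groups <- split(subsets, canon)
  cls <- purrr::map(groups, function(members) {
    keys <- vapply(members, subset_key, character(1))
    members <- members[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
    rep <- members[[which(keys == min(keys))[1]]]
    tibble(
      dar = 2L * length(rep),
      n_lchc_reduced = sum(site[rep] == "LC-HC"),
      n_members = length(members),
      representative = list(rep),
      members = list(members)
    )
  })
  out <- dplyr::bind_rows(cls)
  out$rep_key <- vapply(out$representative,
                        function(s) paste(sort(s), collapse = "|"), character(1))
  out <- dplyr::arrange(out, .data$dar, dplyr::desc(.data$n_lchc_reduced),
                        .data$rep_key)
  out$rep_key <- NULL
  # label: dar value, plus a/b/c suffix when a load has several classes
  out <- dplyr::group_by(out, .data$dar)
  out <- dplyr::mutate(out,
    label = if (dplyr::n() == 1L) as.character(.data$dar[1]) else
      paste0(.data$dar, letters[dplyr::row_number()])
  )
  out <- dplyr::ungroup(out)
  out <- dplyr::relocate(out, "label")
  class(out) <- c("isoform_classes", class(out))
  out
}

# Fetch one isoform row by label (or pass a one-row slice through).
.isoform_row <- function(isoform, assembly) {
  if (is.character(isoform)) {
    iso <- enumerate_isoforms(assembly)
    row <- iso[iso$label == isoform, ]
    if (nrow(row) == 0L) {
      abort(paste0("Unknown isoform label: ", isoform, " (have: ",
                   paste(iso$label, collapse = ", "), ")"))
    }
    row
  } else {
    stopifnot(is.data.frame(isoform), nrow(isoform) == 1L)
    isoform
  }
}

#' Mass of a covalent sub-unit
#'
#' A sub-unit is a multiset of chain instances held together by
#' `internal_intact_bonds` disulfides and carrying `drug_count` drugs. Its
#' mass is the sum of the reduced chain masses, plus glycoform deltas, plus
#' drugs, minus one disulfide decrement per internal intact bond.
#'
#' @param assembly An [adc_assembly()].
#' @param chains Character vector of chain instance ids (e.g. `c("L1")` or
#'   `c("H1", "H2", "L2")`).
#' @param drug_count Number of conjugated drugs on the sub-unit.
#' @param internal_intact_bonds Number of intact inter-chain bonds inside the
#'   sub-unit.
#' @param glycoform Glycoform name applied to every heavy chain in the
#'   sub-unit (must exist in the heavy-chain glycoform table). Ignored for
#'   light-only sub-units when `NULL`; naming a glycoform for a sub-unit with
#'   no heavy chain is an error.
#' @return Average mass in Da.
#' @examples
#' asm <- fixture_igg1()
#' subunit_mass(asm, "L1", drug_count = 1)                  # 23,580.0
#' subunit_mass(asm, "H1", drug_count = 3, glycoform = "G0F") # 51,630.6
#' @export
subunit_mass <- function(assembly, chains, drug_count = 0,
                         internal_intact_bonds = 0, glycoform = NULL) {
  stopifnot(inherits(assembly, "adc_assembly"))
  specs <- assembly$chains[chains]
  if (any(vapply(specs, is.null, logical(1)))) {
    abort(paste0("Unknown chain instance: ",
                 paste(chains[vapply(specs, is.null, logical(1))], collapse = ", ")))
  }
  roles <- vapply(specs, function(s) s$role, character(1))
  n_heavy <- sum(roles == "heavy")
  glyco_delta <- 0
  if (!is.null(glycoform)) {
    if (n_heavy == 0L) {
      abort(paste0("Glycoform '", glycoform,
                   "' named for a sub-unit with no heavy chain"))
    }
    heavy_spec <- specs[[which(roles == "heavy")[1]]]
    gl <- heavy_spec$glycoforms
    hit <- gl$delta[gl$name == glycoform]
    if (length(hit) == 0L) abort(paste0("Unknown glycoform: ", glycoform))
    glyco_delta <- n_heavy * hit
  }
  base <- sum(vapply(specs, function(s) s$reduced_average_mass, numeric(1)))
  base + glyco_delta + drug_count * assembly$drug$average_mass -
    internal_intact_bonds * assembly$disulfide_decrement
}

#' Dissociation signature of an isoform
#'
#' Under denaturing conditions an isoform dissociates into the connected
#' components of its chain graph over the intact inter-chain bonds. Each
#' reduced bond deposits one drug at each of its two endpoint cysteines, so
#' a component's drug count is the number of reduced-bond endpoints it
#' contains. Component masses follow [subunit_mass()]; masses within
#' `merge_tol` are merged into one "unique" mass (below chromatographic and
#' deconvolution resolution at these masses).
#'
#' @param isoform An isoform label (e.g. `"6b"`) or a one-row slice of
#'   [enumerate_isoforms()] output.
#' @param assembly An [adc_assembly()].
#' @param glycoform Glycoform name applied to every heavy chain (default:
#'   first configured glycoform, or none if the assembly has no glycoforms).
#' @param merge_tol Da; masses closer than this count as one unique mass.
#' @return A tibble of class `dissociation_signature` with one row per
#'   sub-unit: `subunit`, `chains` (list-column), `n_copies`, `drug_count`,
#'   `internal_intact_bonds`, `glycoform`, `mass`. Attributes `isoform`,
#'   `dar` and `unique_masses` (sorted, merged) are attached.
#' @examples
#' dissociate("8", fixture_igg1())   # light+1 and heavy+3
#' dissociate("6b", fixture_igg1())  # 3 unique masses
#' @export
dissociate <- function(isoform, assembly, glycoform = NULL, merge_tol = 0.5) {
  row <- .isoform_row(isoform, assembly)
  reduced <- row$representative[[1]]
  chains <- names(assembly$chains)
  has_glyco <- any(vapply(assembly$chains,
                          function(s) nrow(s$glycoforms) > 0, logical(1)))
  if (is.null(glycoform) && has_glyco) {
    heavy <- assembly$chains[[which(vapply(assembly$chains,
                                           function(s) s$role, character(1)) == "heavy")[1]]]
    glycoform <- heavy$glycoforms$name[1]
  }

  intact <- assembly$bonds[!assembly$bonds$id %in% reduced, ]
  comp <- .connected_components(chains, intact)

  # one drug per reduced-bond endpoint
  red_bonds <- assembly$bonds[assembly$bonds$id %in% reduced, ]
  drug_sites <- c(red_bonds$chain_a, red_bonds$chain_b)

  sub <- purrr::map(comp, function(members) {
    internal <- sum(intact$chain_a %in% members & intact$chain_b %in% members)
    drugs <- sum(drug_sites %in% members)
    roles <- vapply(assembly$chains[members], function(s) s$role, character(1))
    gl <- if (any(roles == "heavy")) glycoform else NULL
    tibble(
      subunit = paste(sort(members), collapse = "+"),
      chains = list(sort(members)),
      drug_count = drugs,
      internal_intact_bonds = internal,
      glycoform = if (is.null(gl)) NA_character_ else gl,
      mass = subunit_mass(assembly, members, drug_count = drugs,
                          internal_intact_bonds = internal, glycoform = gl)
    )
  })
  sig <- dplyr::bind_rows(sub)
  sig <- dplyr::arrange(sig, .data$mass, .data$subunit)
  # collapse symmetry-identical copies (same composition class & mass)
  sig <- dplyr::mutate(
    dplyr::group_by(sig, key = paste(.data$mass, .data$drug_count,
                                     .data$internal_intact_bonds,
                                     vapply(.data$chains, length, integer(1)))),
    n_copies = dplyr::n()
  )
  sig <- dplyr::ungroup(sig)
  sig <- dplyr::distinct(sig, .data$key, .keep_all = TRUE)
  sig$key <- NULL
  attr(sig, "isoform") <- row$label
  attr(sig, "dar") <- row$dar
  attr(sig, "unique_masses") <- merge_masses(rep(sig$mass, sig$n_copies),
                                             tol = merge_tol)
  class(sig) <- c("dissociation_signature", class(sig))
  sig
}

# Connected components of the chain graph under a set of intact bonds.
.connected_components <- function(nodes, bonds) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(bonds))) {
    ra <- find(bonds$chain_a[i]); rb <- find(bonds$chain_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  unname(split(nodes, roots))
}

#' Merge masses within a tolerance into unique representatives
#'
#' Single-linkage clustering on sorted masses: consecutive masses closer than
#' `tol` belong to one cluster; the cluster mean is its representative.
#'
#' @param masses Numeric vector of masses (Da).
#' @param tol Merge tolerance in Da.
#' @return Sorted numeric vector of unique representative masses.
#' @export
merge_masses <- function(masses, tol = 0.5) {
  if (length(masses) == 0L) return(numeric(0))
  m <- sort(masses)
  grp <- cumsum(c(1, diff(m) > tol))
  as.numeric(tapply(m, grp, mean))
}

#' Intact mass of an isoform
#'
#' Sum of all chain masses and glycoform deltas, plus one drug per reduced
#' cysteine, minus one disulfide decrement per *intact* inter-chain bond.
#' Equals the sum of the isoform's dissociation-signature sub-unit masses by
#' construction (mass conservation).
#'
#' @inheritParams dissociate
#' @return Average mass in Da.
#' @examples
#' intact_mass("0", fixture_igg1()) # ~147.4 kDa
#' @export
intact_mass <- function(isoform, assembly, glycoform = NULL) {
  row <- .isoform_row(isoform, assembly)
  sig <- dissociate(row, assembly, glycoform = glycoform)
  sum(sig$mass * sig$n_copies)
}

#' Signature library as a flat table
#'
#' Expands every isoform class of an assembly into its per-sub-unit masses
#' for each configured glycoform; suitable for CSV export.
#'
#' @param assembly An [adc_assembly()].
#' @param merge_tol Unique-mass merge tolerance in Da.
#' @return Tibble with columns `isoform_label`, `dar`, `subunit_composition`,
#'   `n_copies`, `drug_count`, `glycoform`, `mass_da`.
#' @export
signature_table <- function(assembly, merge_tol = 0.5) {
  iso <- enumerate_isoforms(assembly)
  heavy_glyco <- assembly$chains[[which(vapply(assembly$chains, function(s) s$role,
                                               character(1)) == "heavy")[1]]]$glycoforms
  glyco_names <- if (nrow(heavy_glyco) > 0) heavy_glyco$name else NA_character_
  purrr::map_dfr(seq_len(nrow(iso)), function(i) {
    purrr::map_dfr(glyco_names, function(g) {
      sig <- dissociate(iso[i, ], assembly,
                        glycoform = if (is.na(g)) NULL else g,
                        merge_tol = merge_tol)
      tibble(
        isoform_label = iso$label[i], dar = iso$dar[i],
        subunit_composition = sig$subunit, n_copies = sig$n_copies,
        drug_count = sig$drug_count, glycoform = sig$glycoform,
        mass_da = round(sig$mass, 1)
      )
    })
  })
}
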