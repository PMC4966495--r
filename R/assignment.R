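# Isoform assignment: match deconvolved sub-unit masses from a heart-cut
# fraction against the enumerated signature library.
#
# The identification logic is two-sided: a fraction is *uniquely* assigned
# to an isoform only when every observed mass is explained by one of the
# isoform's expected sub-unit masses (directly, as a glycoform variant, or
# as a single known modification satellite) AND every expected unique mass
# is actually observed. The full complement is what makes a sub-unit pair
# diagnostic: light+1 alone is shared by most drug-loaded isoforms.

#' Build the isoform signature library
#'
#' Enumerates all isoform classes of the assembly and expands each sub-unit
#' mass over the configured heavy-chain glycoforms. Sub-units sharing a
#' composition count as one expected unique mass group; any glycoform
#' variant of the group satisfies the "observed" requirement.
#'
#' @param assembly An [adc_assembly()].
#' @param merge_tol Unique-mass merge tolerance in Da.
#' @return A tibble of class `signature_library` with columns
#'   `isoform_label`, `dar`, `group` (expected-mass group index within the
#'   isoform), `subunit_composition`, `glycoform`, `mass`. The first
#'   configured glycoform is the reference variant (`is_reference`).
#' @examples
#' build_library(fixture_igg1())
#' @export
build_library <- function(assembly, merge_tol = 0.5) {
  iso <- enumerate_isoforms(assembly)
  heavy_idx <- which(vapply(assembly$chains, function(s) s$role,
                            character(1)) == "heavy")[1]
  glyco <- assembly$chains[[heavy_idx]]$glycoforms
  glyco_names <- if (nrow(glyco) > 0) glyco$name else NA_character_

  lib <- purrr::map_dfr(seq_len(nrow(iso)), function(i) {
    ref <- dissociate(iso[i, ], assembly,
                      glycoform = if (is.na(glyco_names[1])) NULL else glyco_names[1],
                      merge_tol = merge_tol)
    purrr::map_dfr(seq_len(nrow(ref)), function(g) {
      has_heavy <- !is.na(ref$glycoform[g])
      variants <- if (has_heavy) glyco_names else NA_character_
      purrr::map_dfr(variants, function(v) {
        m <- if (has_heavy && v != glyco_names[1]) {
          sig_v <- dissociate(iso[i, ], assembly, glycoform = v,
                              merge_tol = merge_tol)
          sig_v$mass[g]
        } else {
          ref$mass[g]
        }
        tibble(
          isoform_label = iso$label[i], dar = iso$dar[i], group = g,
          subunit_composition = ref$subunit[g],
          glycoform = v, is_reference = is.na(v) | v == glyco_names[1],
          mass = m
        )
      })
    })
  })
  structure(lib, class = c("signature_library", class(lib)))
}

# absolute match tolerance at a given mass: ppm criterion with a Da floor
# (deconvolution grid resolution dominates below ~100 kDa at 10 ppm)
.match_tol <- function(mass, ppm_tolerance, da_floor) {
  pmax(ppm_tolerance * 1e-6 * mass, da_floor)
}

#' Match observed masses against the signature library
#'
#' Every candidate isoform is scored by how many observed masses it leaves
#' unexplained and how many of its expected unique mass groups go
#' unobserved; candidates are ranked by (unexplained + unobserved, mean
#' absolute ppm error of the direct matches). The assignment is flagged
#' unique when exactly one candidate explains everything and misses nothing.
#'
#' @param observed Numeric vector of deconvolved neutral masses (Da).
#' @param library A [build_library()] result.
#' @param ppm_tolerance Match tolerance in ppm (default 10).
#' @param da_floor Absolute tolerance floor in Da (default 1.0).
#' @param modifications A [modification_table()]; a single modification
#'   satellite may co-explain an observed mass alongside its parent without
#'   counting as unexplained.
#' @return A list of class `adc_assignment` with elements `observed`,
#'   `candidates` (tibble: `isoform_label`, `dar`, `n_unexplained`,
#'   `n_unobserved`, `mean_abs_ppm`, `matches` list-column) and `unique`
#'   (logical).
#' @examples
#' lib <- build_library(fixture_igg1())
#' match_observed(c(23580.0, 51630.6), lib)
#' @export
match_observed <- function(observed, library, ppm_tolerance = 10,
                           da_floor = 1.0,
                           modifications = modification_table()) {
  if (length(observed) == 0L) abort("No observed masses: nothing to assign")
  if (ppm_tolerance <= 0) abort("ppm_tolerance must be > 0")
  stopifnot(inherits(library, "signature_library"))

  cands <- purrr::map_dfr(split(library, library$isoform_label), function(lib_i) {
    groups <- split(lib_i, lib_i$group)
    match_rows <- list()
    explained <- rep(FALSE, length(observed))
    observed_groups <- rep(FALSE, length(groups))
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      for (oi in seq_along(observed)) {
        o <- observed[oi]
        tol <- .match_tol(g$mass, ppm_tolerance, da_floor)
        direct <- which(abs(o - g$mass) <= tol)
        if (length(direct) > 0L) {
          v <- direct[which.min(abs(o - g$mass[direct]))]
          explained[oi] <- TRUE
          observed_groups[gi] <- TRUE
          match_rows[[length(match_rows) + 1L]] <- tibble(
            observed = o, predicted = g$mass[v],
            ppm = ppm_error(o, g$mass[v]),
            glycoform = g$glycoform[v], modification = NA_character_
          )
          next
        }
        # modification satellite of one of the group's variants
        for (mi in seq_len(nrow(modifications))) {
          shifted <- g$mass + modifications$delta[mi]
          tol_m <- tol + modifications$tolerance[mi]
          sat <- which(abs(o - shifted) <= tol_m)
          if (length(sat) > 0L) {
            v <- sat[which.min(abs(o - shifted[sat]))]
            explained[oi] <- TRUE
            observed_groups[gi] <- TRUE
            match_rows[[length(match_rows) + 1L]] <- tibble(
              observed = o, predicted = g$mass[v],
              ppm = ppm_error(o, shifted[v]),
              glycoform = g$glycoform[v],
              modification = modifications$name[mi]
            )
            break
          }
        }
      }
    }
    matches <- if (length(match_rows) > 0) dplyr::bind_rows(match_rows) else
      tibble(observed = numeric(0), predicted = numeric(0), ppm = numeric(0),
             glycoform = character(0), modification = character(0))
    direct_ppm <- abs(matches$ppm[is.na(matches$modification)])
    tibble(
      isoform_label = lib_i$isoform_label[1],
      dar = lib_i$dar[1],
      n_unexplained = sum(!explained),
      n_unobserved = sum(!observed_groups),
      mean_abs_ppm = if (length(direct_ppm) > 0) mean(direct_ppm) else Inf,
      matches = list(matches)
    )
  })
  cands <- dplyr::arrange(cands,
                          .data$n_unexplained + .data$n_unobserved,
                          .data$mean_abs_ppm)
  complete <- cands$n_unexplained == 0 & cands$n_unobserved == 0
  structure(
    list(observed = observed, candidates = cands,
         unique = sum(complete) == 1L,
         best = if (any(complete)) cands$isoform_label[which(complete)[1]]
                else NA_character_),
    class = "adc_assignment"
  )
}

#' @export
print.adc_assignment <- function(x, ...) {
  cat("<adc_assignment> ", length(x$observed), " observed mass(es); ",
      if (x$unique) paste0("UNIQUE -> ", x$best) else "not unique", "\n",
      sep = "")
  print(x$candidates[c("isoform_label", "dar", "n_unexplained",
                       "n_unobserved", "mean_abs_ppm")], n = 5)
  invisible(x)
}

#' Ambiguity analysis of a signature library
#'
#' Pairwise comparison of the reference (first-glycoform) unique-mass sets
#' of all isoforms. Reports any pair whose signatures are identical within
#' tolerance (indistinguishable by sub-unit mass) and any isoform whose
#' signature is a proper subset of another's (a co-elution confound: seeing
#' only the smaller set cannot exclude the larger isoform; for the standard
#' IgG1 fixture, DAR 8's pair is a subset of 6b's triple).
#'
#' @param library A [build_library()] result.
#' @param ppm_tolerance,da_floor Match tolerance (see [match_observed()]).
#' @return Tibble with columns `isoform_a`, `isoform_b`, `relation`
#'   (`"identical"` or `"subset"`, meaning a's signature is contained in
#'   b's). Empty when the library is unambiguous.
#' @export
uniqueness_analysis <- function(library, ppm_tolerance = 10, da_floor = 1.0) {
  stopifnot(inherits(library, "signature_library"))
  ref <- library[library$is_reference, ]
  sets <- lapply(split(ref, ref$isoform_label), function(x) sort(x$mass))
  labs <- names(sets)
  out <- list()
  contained <- function(a, b) {
    all(vapply(a, function(m) {
      any(abs(m - b) <= .match_tol(b, ppm_tolerance, da_floor))
    }, logical(1)))
  }
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i == j) next
      a <- sets[[i]]; b <- sets[[j]]
      if (length(a) == length(b) && i < j && contained(a, b) && contained(b, a)) {
        out[[length(out) + 1L]] <- tibble(isoform_a = labs[i],
                                          isoform_b = labs[j],
                                          relation = "identical")
      } else if (length(a) < length(b) && contained(a, b)) {
        out[[length(out) + 1L]] <- tibble(isoform_a = labs[i],
                                          isoform_b = labs[j],
                                          relation = "subset")
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(isoform_a = character(0), isoform_b = character(0),
                  relation = character(0)))
  }
  dplyr::bind_rows(out)
}
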