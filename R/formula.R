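# Average molecular mass from elemental composition.
#
# Standard average atomic weights (IUPAC 2021 abridged values). Average (not
# monoisotopic) masses are used throughout the package: continuum intact-protein
# spectra of 20-150 kDa species deconvolute to average masses.
.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  Na = 22.990, K = 39.098, Cl = 35.45, F = 18.998, Br = 79.904, I = 126.904,
  Se = 78.971, Fe = 55.845, Zn = 65.38, Cu = 63.546, Ca = 40.078, Mg = 24.305
)

#' Parse a molecular formula string
#'
#' Converts a Hill-style formula string such as `"C23H24N2O3"` into a named
#' integer vector of element counts. Only element symbols followed by an
#' optional count are supported (no parentheses, charges or isotope labels);
#' that is sufficient for small-molecule drug linkers.
#'
#' @param formula A single formula string, e.g. `"C23H24N2O3"`. An empty
#'   string yields an empty (zero-mass) composition.
#' @return A named integer vector of element counts.
#' @examples
#' parse_formula("C23H24N2O3")
#' parse_formula("H2O")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  formula <- gsub("[[:space:]_]", "", formula)
  if (!nzchar(formula)) {
    return(setNames(integer(0), character(0)))
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    abort(paste0("Cannot parse formula: '", formula, "'"))
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  out <- tapply(counts, elements, sum)
  setNames(as.integer(out), names(out))
}

#' Average mass of a chemical formula
#'
#' Computes the average molecular mass (Da) of an elemental composition using
#' standard average atomic weights. The empty formula has mass 0.
#'
#' @param formula Either a formula string (see [parse_formula()]) or a named
#'   numeric vector of element counts.
#' @return Average mass in Da.
#' @examples
#' average_mass("C23H24N2O3") # maleimide drug mimic, 376.46 Da
#' average_mass("H2O")
#' @export
average_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0L) {
    return(0)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort("Element counts must be a named vector")
  }
  if (any(counts < 0)) {
    abort("Element counts must be non-negative")
  }
  unknown <- setdiff(names(counts), names(.atomic_weights))
  if (length(unknown) > 0L) {
    abort(paste0("Unknown element symbol(s): ", paste(unknown, collapse = ", ")))
  }
  sum(counts * .atomic_weights[names(counts)])
}
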