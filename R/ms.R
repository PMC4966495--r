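# Continuum ESI spectrum tools: peak picking, charge-comb deconvolution to
# neutral average masses, ppm errors and modification-delta matching.

PROTON_MASS <- 1.00728 # average proton mass, positive-mode charge carrier

#' Construct a mass spectrum
#'
#' @param data Data frame with numeric columns `mz` (Th, strictly
#'   increasing) and `intensity`.
#' @param mz_range Acquisition window (Th); default 500-4,000.
#' @return A tibble of class `mass_spectrum`.
#' @export
as_mass_spectrum <- function(data, mz_range = c(500, 4000)) {
  data <- as_tibble(data)
  if (!all(c("mz", "intensity") %in% names(data))) {
    abort("A mass spectrum needs `mz` and `intensity` columns")
  }
  if (nrow(data) == 0L) abort("Empty spectrum")
  if (any(diff(data$mz) <= 0)) abort("m/z must be strictly increasing")
  structure(data[c("mz", "intensity")],
            class = c("mass_spectrum", class(data)),
            mz_range = mz_range)
}

#' Pick centroids from a continuum spectrum
#'
#' Contiguous runs of points above threshold become one centroid at their
#' intensity-weighted m/z center. The threshold is `snr_threshold` times a
#' robust noise estimate (median absolute successive difference); for
#' noise-free spectra a small floor relative to the base peak is used.
#'
#' @param spec A [as_mass_spectrum()] object.
#' @param snr_threshold Signal-to-noise multiple for the picking threshold.
#' @return Tibble with columns `mz`, `intensity` (summed) sorted by m/z.
#' @export
pick_peaks <- function(spec, snr_threshold = 5) {
  if (!inherits(spec, "mass_spectrum")) spec <- as_mass_spectrum(spec)
  y <- spec$intensity
  if (all(y <= 0)) {
    return(tibble(mz = numeric(0), intensity = numeric(0)))
  }
  noise <- stats::median(abs(diff(y))) / sqrt(2)
  threshold <- max(snr_threshold * noise, 1e-6 * max(y))
  above <- y > threshold
  if (!any(above)) {
    return(tibble(mz = numeric(0), intensity = numeric(0)))
  }
  run <- cumsum(c(above[1], diff(above) == 1))
  run[!above] <- NA
  df <- tibble(mz = spec$mz[above], intensity = y[above],
               run = run[above])
  out <- dplyr::summarise(dplyr::group_by(df, .data$run),
                          mz = sum(.data$mz * .data$intensity) / sum(.data$intensity),
                          intensity = sum(.data$intensity), .groups = "drop")
  dplyr::arrange(out[c("mz", "intensity")], .data$mz)
}

#' Signed mass error in parts per million
#'
#' @param observed,predicted Masses in Da; `predicted` must be > 0.
#' @return `1e6 * (observed - predicted) / predicted`.
#' @examples
#' ppm_error(100001, 100000) # +10
#' @export
ppm_error <- function(observed, predicted) {
  if (any(predicted <= 0)) abort("predicted mass must be > 0")
  1e6 * (observed - predicted) / predicted
}

#' Deconvolve a charge-state envelope to neutral average masses
#'
#' Transparent charge-comb scoring with greedy envelope subtraction. For
#' each candidate neutral mass M on a grid, the score is the sum over
#' charges z of the (linearly interpolated) continuum intensity at
#' m/z = (M + z * 1.00728) / z, restricted to the acquisition window. The
#' best-scoring local maximum is refined on a fine local grid with a final
#' quadratic interpolation of the apex, accepted when at least
#' `min_support` contiguous charge states carry appreciable intensity (a
#' single peak cannot determine a charge, and a genuine electrospray
#' envelope is contiguous in z), and its comb teeth are then subtracted
#' from the residual spectrum (each tooth removed down to its enclosing
#' valleys) before the next species is searched.
#'
#' The greedy subtraction is what keeps chance two-tooth coincidences,
#' harmonics (2M aligns with M at every second charge) and subharmonics
#' (M/2) from surfacing as spurious masses: they share their teeth with the
#' true species and have nothing left to score once it is subtracted.
#' `filter_harmonics` remains as a cheap backstop on the accepted list.
#'
#' @param spec A [as_mass_spectrum()] object.
#' @param mass_range Numeric length-2: neutral mass search window in Da.
#' @param charge_range Integer length-2: inclusive charge range.
#' @param grid_step Mass grid step in Da (default 0.1).
#' @param proton Charge carrier mass (Da).
#' @param min_support Minimum number of contiguous supporting charge states.
#' @param support_frac A charge supports a mass when its comb-tooth
#'   intensity is at least this fraction of the strongest tooth for that
#'   mass.
#' @param min_score_frac Stop extracting species once the best remaining
#'   score falls below this fraction of the first extraction's score.
#' @param max_species Upper bound on the number of extracted masses.
#' @param dedupe_window Candidates closer than this (Da) to an already
#'   accepted mass are treated as residue of that species: subtracted but
#'   not reported.
#' @param filter_harmonics Drop any accepted mass whose x2/x3 multiple or
#'   /2 /3 submultiple matches a stronger accepted mass.
#' @return A tibble of class `deconvolved_masses` with columns
#'   `neutral_mass`, `score`, `n_charges`, `charges` (list-column), sorted
#'   by decreasing score.
#' @export
deconvolve <- function(spec, mass_range, charge_range, grid_step = 0.1,
                       proton = PROTON_MASS, min_support = 2,
                       support_frac = 0.1, min_score_frac = 0.1,
                       max_species = 10, dedupe_window = 5,
                       filter_harmonics = TRUE) {
  if (!inherits(spec, "mass_spectrum")) spec <- as_mass_spectrum(spec)
  if (length(mass_range) != 2L || diff(mass_range) <= 0) {
    abort("mass_range must be an increasing length-2 vector")
  }
  if (grid_step <= 0) abort("grid_step must be > 0")
  zs <- seq.int(charge_range[1], charge_range[2])
  if (length(zs) < 1L || any(zs < 1L)) abort("charge_range must be positive")
  window <- attr(spec, "mz_range") %||% range(spec$mz)

  mz <- spec$mz
  residual <- spec$intensity
  grid <- seq(mass_range[1], mass_range[2], by = grid_step)
  # tooth positions on the coarse grid, fixed across iterations
  xout <- lapply(zs, function(z) (grid + z * proton) / z)
  inwin <- lapply(xout, function(x) x >= window[1] & x <= window[2])

  comb_score <- function(res_fun, masses) {
    s <- numeric(length(masses))
    for (z in zs) {
      x <- (masses + z * proton) / z
      v <- res_fun(x)
      v[x < window[1] | x > window[2]] <- 0
      s <- s + v
    }
    s
  }

  # valley-bounded removal of the comb teeth of mass m for charges `sup`
  # from the residual; returns TRUE when anything was removed
  subtract_teeth <- function(m, sup) {
    removed <- FALSE
    for (z in sup) {
      x <- (m + z * proton) / z
      if (x < window[1] || x > window[2]) next
      i0 <- which.min(abs(mz - x))
      if (residual[i0] <= 0) next
      lo <- i0
      while (lo > 1L && residual[lo - 1L] <= residual[lo] &&
             residual[lo - 1L] > 0) lo <- lo - 1L
      hi <- i0
      while (hi < length(residual) && residual[hi + 1L] <= residual[hi] &&
             residual[hi + 1L] > 0) hi <- hi + 1L
      residual[lo:hi] <<- 0
      removed <- TRUE
    }
    removed
  }

  found <- list()
  stop_score <- NA_real_
  for (iter in seq_len(4L * max_species)) {
    if (length(found) >= max_species) break
    res_fun <- stats::approxfun(mz, residual, yleft = 0, yright = 0)
    score <- numeric(length(grid))
    for (k in seq_along(zs)) {
      v <- res_fun(xout[[k]])
      v[!inwin[[k]]] <- 0
      score <- score + v
    }
    if (all(score <= 0)) break
    apex <- .local_maxima(score)
    if (length(apex) == 0L) break
    apex <- apex[order(score[apex], decreasing = TRUE)]
    if (is.na(stop_score)) stop_score <- min_score_frac * score[apex[1]]
    if (score[apex[1]] < stop_score) break

    # walk the ranked candidates and take the strongest one whose
    # supporting charges form a contiguous run (harmonics align only at
    # every k-th charge and are skipped here, not subtracted)
    support_at <- function(m) {
      th <- vapply(zs, function(z) {
        x <- (m + z * proton) / z
        if (x < window[1] || x > window[2]) return(0)
        res_fun(x)
      }, numeric(1))
      if (max(th) <= 0) return(list(th = th, sup = integer(0)))
      flags <- th >= support_frac * max(th)
      runs <- rle(flags)
      longest <- which(runs$values &
                         runs$lengths == max(runs$lengths[runs$values]))[1]
      run_end <- cumsum(runs$lengths)[longest]
      list(th = th, sup = zs[(run_end - runs$lengths[longest] + 1L):run_end])
    }
    prev_masses <- vapply(found, function(x) x$neutral_mass, numeric(1))
    best <- NA_integer_
    residue <- FALSE
    for (i in head(apex, 50L)) {
      if (score[i] < stop_score) break
      sup_i <- support_at(grid[i])$sup
      if (length(prev_masses) > 0 &&
          any(abs(grid[i] - prev_masses) < dedupe_window)) {
        # residue of an already extracted species (noise left a fragment
        # of a tooth standing): subtract it, do not report it again
        if (length(sup_i) > 0 && subtract_teeth(grid[i], sup_i)) {
          residue <- TRUE
          break
        }
        next
      }
      if (length(sup_i) >= min_support) {
        best <- i
        break
      }
    }
    if (residue) next
    if (is.na(best)) break

    # local fine search, then a least-squares quadratic fit through the top
    # of the score curve (averages out interpolation ripple, which a
    # 3-point parabola cannot)
    half_width <- max(3, 2 * grid_step)
    fine_step <- min(grid_step / 2, 0.05)
    fine <- seq(grid[best] - half_width, grid[best] + half_width,
                by = fine_step)
    fs <- comb_score(res_fun, fine)
    fi <- which.max(fs)
    m <- fine[fi]
    top <- which(fs >= 0.9 * fs[fi])
    # keep only the contiguous stretch around the apex
    brk <- which(diff(top) > 1L)
    if (length(brk) > 0L) {
      seg_start <- c(1L, brk + 1L)
      seg_end <- c(brk, length(top))
      seg <- which(top[seg_start] <= fi & fi <= top[seg_end])[1]
      top <- top[seg_start[seg]:seg_end[seg]]
    }
    if (length(top) >= 5L) {
      xc <- fine[top] - m
      co <- stats::coef(stats::lm(fs[top] ~ xc + I(xc^2)))
      if (!anyNA(co) && co[[3]] < 0) {
        m <- m - co[[2]] / (2 * co[[3]])
      }
    }

    sup_ref <- support_at(m)
    th <- sup_ref$th
    sup <- sup_ref$sup
    if (length(sup) < min_support) {
      # refinement drifted off support; keep the coarse position
      m <- grid[best]
      sup_ref <- support_at(m)
      th <- sup_ref$th
      sup <- sup_ref$sup
      if (length(sup) < min_support) break
    }
    found[[length(found) + 1L]] <- tibble(
      neutral_mass = m, score = sum(th),
      n_charges = length(sup), charges = list(sup))
    # subtract only the supporting teeth: out-of-envelope comb positions
    # belong to other species and must stay in the residual
    if (!subtract_teeth(m, sup)) break
  }

  if (length(found) == 0L) return(.empty_deconv())
  cand <- dplyr::arrange(dplyr::bind_rows(found), dplyr::desc(.data$score))
  if (filter_harmonics && nrow(cand) > 1L) {
    cand <- .drop_harmonics(cand)
  }
  structure(cand, class = c("deconvolved_masses", class(cand)))
}

.empty_deconv <- function() {
  out <- tibble(neutral_mass = numeric(0), score = numeric(0),
                n_charges = integer(0), charges = list())
  structure(out, class = c("deconvolved_masses", class(out)))
}

# Drop masses whose small-integer multiple or submultiple coincides with a
# stronger accepted mass (tolerance 2 Da per harmonic order).
.drop_harmonics <- function(cand) {
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))[-1]) {
    m <- cand$neutral_mass[i]
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      M <- cand$neutral_mass[j]
      for (k in 2:3) {
        if (abs(m * k - M) <= 2 * k || abs(M * k - m) <= 2 * k) {
          keep[i] <- FALSE
        }
      }
    }
  }
  cand[keep, ]
}

#' Table of known mass-shift modifications
#'
#' Default entries: dehydration (water loss, -18.02 Da +- 1.5) and one
#' hexose (the G1F vs G0F glycoform spacing, +162.14 Da +- 0.8). Entry
#' deltas must stay distinct beyond their combined tolerances.
#'
#' @param entries Optional tibble with columns `name`, `delta`, `tolerance`
#'   replacing the defaults.
#' @return Tibble of class `modification_table`.
#' @export
modification_table <- function(entries = NULL) {
  if (is.null(entries)) {
    entries <- tibble(
      name = c("dehydration", "hexose"),
      delta = c(-18.02, 162.14),
      tolerance = c(1.5, 0.8)
    )
  }
  entries <- as_tibble(entries)
  stopifnot(all(c("name", "delta", "tolerance") %in% names(entries)))
  if (any(entries$tolerance <= 0)) abort("Modification tolerances must be > 0")
  if (nrow(entries) > 1L) {
    for (i in seq_len(nrow(entries) - 1L)) {
      for (j in (i + 1L):nrow(entries)) {
        if (abs(entries$delta[i] - entries$delta[j]) <=
            entries$tolerance[i] + entries$tolerance[j]) {
          abort(paste0("Overlapping modification entries: ",
                       entries$name[i], " and ", entries$name[j]))
        }
      }
    }
  }
  structure(entries, class = c("modification_table", class(entries)))
}

#' Explain an observed mass delta as a known modification
#'
#' @param observed_delta Observed mass difference in Da (signed).
#' @param table A [modification_table()].
#' @return The matching modification name, or `NA_character_` when no entry
#'   matches. Matches are unique by the table's non-overlap invariant.
#' @examples
#' explain_mass_delta(-17.4) # dehydration
#' explain_mass_delta(162.1) # hexose
#' @export
explain_mass_delta <- function(observed_delta, table = modification_table()) {
  if (!inherits(table, "modification_table")) table <- modification_table(table)
  hit <- which(abs(observed_delta - table$delta) <= table$tolerance)
  if (length(hit) == 0L) NA_character_ else table$name[hit[1]]
}
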