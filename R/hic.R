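# First-dimension HIC quantitation: peak detection, integration, relative
# areas, per-load DAR contributions and heart-cut bookkeeping.

#' Construct a chromatogram
#'
#' @param data Data frame with numeric columns `time` (minutes, strictly
#'   increasing, uniform grid) and `intensity` (absorbance units).
#' @param wavelength_nm,sampling_rate_hz,batch,replicate Acquisition
#'   metadata stored as attributes.
#' @return A tibble of class `chromatogram`.
#' @export
as_chromatogram <- function(data, wavelength_nm = 220, sampling_rate_hz = 20,
                            batch = NA_character_, replicate = NA_integer_) {
  data <- as_tibble(data)
  if (!all(c("time", "intensity") %in% names(data))) {
    abort("A chromatogram needs `time` and `intensity` columns")
  }
  if (nrow(data) < 3L) abort("A chromatogram needs at least 3 samples")
  if (any(!is.finite(data$time)) || any(diff(data$time) <= 0)) {
    abort("Chromatogram time must be finite and strictly increasing")
  }
  if (any(!is.finite(data$intensity))) abort("Chromatogram intensity must be finite")
  structure(
    data[c("time", "intensity")],
    class = c("chromatogram", class(data)),
    metadata = list(wavelength_nm = wavelength_nm,
                    sampling_rate_hz = sampling_rate_hz,
                    batch = batch, replicate = replicate)
  )
}

# trapezoidal integral of y over x between index bounds
.trapz <- function(x, y, i = 1L, j = length(x)) {
  idx <- i:j
  sum(diff(x[idx]) * (head(y[idx], -1) + tail(y[idx], -1)) / 2)
}

#' Detect and integrate chromatographic peaks
#'
#' Local maxima of the baseline-corrected trace above a prominence threshold
#' become peak apices. The boundary between two adjacent apices is the valley
#' minimum between them (perpendicular-drop splitting of partially resolved
#' shoulders); outer boundaries are placed where the trace returns to
#' baseline. Areas are trapezoidal integrals of the baseline-corrected trace;
#' the baseline is a constant offset estimated from the first and last 5% of
#' the run.
#'
#' @param chrom A [as_chromatogram()] object (or data frame with `time`,
#'   `intensity`).
#' @param min_prominence Minimum topographic prominence, as a fraction of the
#'   tallest baseline-corrected intensity, for an apex to count as a peak.
#' @param min_width Minimum peak width (minutes); narrower detections are
#'   discarded as spikes.
#' @param baseline_frac Fraction of the run at each end used to estimate the
#'   constant baseline.
#' @param floor_frac Fraction of apex height at which the trace is considered
#'   returned to baseline when placing outer boundaries.
#' @return A tibble of class `peak_table` with columns `label` (A, B, ... in
#'   elution order), `apex_time`, `start_time`, `end_time`, `height`, `area`
#'   and `relative_area` (percent of total integrated area).
#' @export
detect_peaks <- function(chrom, min_prominence = 0.005, min_width = 0.02,
                         baseline_frac = 0.05, floor_frac = 0.001) {
  if (!inherits(chrom, "chromatogram")) chrom <- as_chromatogram(chrom)
  t <- chrom$time
  n_edge <- max(1L, floor(baseline_frac * length(t)))
  baseline <- mean(c(head(chrom$intensity, n_edge), tail(chrom$intensity, n_edge)))
  y <- chrom$intensity - baseline

  apex <- .local_maxima(y)
  if (length(apex) == 0L) {
    return(.empty_peak_table(baseline))
  }
  prom <- .prominence(y, apex)
  keep <- prom >= min_prominence * max(y)
  apex <- apex[keep]
  for (pass in 1:2) {
    if (length(apex) == 0L) return(.empty_peak_table(baseline))
    bounds <- .peak_bounds(y, sort(apex), floor_frac)
    widths <- t[bounds$end] - t[bounds$start]
    if (all(widths >= min_width) || pass == 2L) break
    apex <- sort(apex)[widths >= min_width]
  }
  apex <- sort(apex)
  area <- vapply(seq_along(apex), function(k) {
    .trapz(t, pmax(y, 0), bounds$start[k], bounds$end[k])
  }, numeric(1))
  labels <- if (length(apex) <= 26L) LETTERS[seq_along(apex)] else
    sprintf("P%02d", seq_along(apex))
  out <- tibble(
    label = labels,
    apex_time = t[apex],
    start_time = t[bounds$start],
    end_time = t[bounds$end],
    height = y[apex],
    area = area,
    relative_area = 100 * area / sum(area)
  )
  structure(out, class = c("peak_table", class(out)),
            baseline = baseline, total_area = sum(area))
}

.empty_peak_table <- function(baseline) {
  out <- tibble(label = character(0), apex_time = numeric(0),
                start_time = numeric(0), end_time = numeric(0),
                height = numeric(0), area = numeric(0),
                relative_area = numeric(0))
  structure(out, class = c("peak_table", class(out)),
            baseline = baseline, total_area = 0)
}

.local_maxima <- function(y) {
  n <- length(y)
  which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
}

# Topographic prominence: height above the higher of the two key saddles
# separating the apex from higher terrain (or the global minimum at edges).
.prominence <- function(y, apex) {
  vapply(apex, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1)]
    right <- if (i < length(y)) y[(i + 1):length(y)] else numeric(0)
    lh <- which(left >= h)
    key_left <- if (length(lh) == 0L) min(c(left, h)) else min(left[max(lh):length(left)])
    rh <- which(right >= h)
    key_right <- if (length(rh) == 0L) min(c(right, h)) else min(right[1:min(rh)])
    h - max(key_left, key_right)
  }, numeric(1))
}

# Valley-to-valley boundaries: shared boundary at the minimum between
# adjacent apices; outer boundaries at baseline return (floor_frac of apex
# height) or the grid edge.
.peak_bounds <- function(y, apex, floor_frac) {
  k <- length(apex)
  start <- integer(k); end <- integer(k)
  for (j in seq_len(k)) {
    floor_j <- floor_frac * y[apex[j]]
    # left
    if (j == 1L) {
      below <- which(y[seq_len(apex[j])] <= floor_j)
      start[j] <- if (length(below) > 0L) max(below) else 1L
    } else {
      seg <- apex[j - 1L]:apex[j]
      vall <- seg[which.min(y[seg])]
      below <- which(y[vall:apex[j]] <= floor_j)
      start[j] <- if (length(below) > 0L) vall + max(below) - 1L else vall
    }
    # right
    if (j == k) {
      below <- which(y[apex[j]:length(y)] <= floor_j)
      end[j] <- if (length(below) > 0L) apex[j] + min(below) - 1L else length(y)
    } else {
      seg <- apex[j]:apex[j + 1L]
      vall <- seg[which.min(y[seg])]
      below <- which(y[apex[j]:vall] <= floor_j)
      end[j] <- if (length(below) > 0L) apex[j] + min(below) - 1L else vall
    }
  }
  list(start = start, end = end)
}

#' Group peak areas by drug load
#'
#' Sums integrated peak areas within each drug-load group and expresses them
#' as percent of the total integrated area.
#'
#' @param peaks A [detect_peaks()] result.
#' @param grouping Named vector or list mapping peak label to drug load
#'   (e.g. `c(A = 0, B = 2, C = 4, D = 4, E = 6, F = 6, G = 6, H = 8)`).
#' @return Tibble with columns `load`, `area`, `area_percent`.
#' @export
group_areas <- function(peaks, grouping) {
  grouping <- unlist(grouping)
  missing <- setdiff(peaks$label, names(grouping))
  if (length(missing) > 0L) {
    abort(paste0("No load assignment for peak(s): ",
                 paste(missing, collapse = ", ")))
  }
  df <- dplyr::mutate(as_tibble(peaks), load = as.integer(grouping[.data$label]))
  out <- dplyr::summarise(dplyr::group_by(df, .data$load),
                          area = sum(.data$area), .groups = "drop")
  dplyr::mutate(dplyr::arrange(out, .data$load),
                area_percent = 100 * .data$area / sum(.data$area))
}

#' Drug-to-antibody ratio from per-load relative areas
#'
#' Each drug-load species contributes `area_percent x load / 100` to the
#' average DAR; the total DAR is the sum of the contributions. UV relative
#' areas are used as relative abundances, which assumes the drug mimic does
#' not change the 220 nm response per conjugate.
#'
#' @param areas Either a tibble with columns `load` and `area_percent` (as
#'   from [group_areas()]) or a named numeric vector of percents with loads
#'   as names.
#' @return A tibble of class `dar_report` with columns `load`,
#'   `area_percent`, `dar_contribution`, and attribute `total_dar`.
#' @examples
#' dar_from_areas(c(`0` = 16.73, `2` = 40.71, `4` = 28.56,
#'                  `6` = 12.54, `8` = 1.50)) # total 2.83
#' @export
dar_from_areas <- function(areas) {
  if (is.numeric(areas) && !is.null(names(areas))) {
    areas <- tibble(load = as.integer(names(areas)),
                    area_percent = unname(areas))
  }
  areas <- as_tibble(areas)
  stopifnot(all(c("load", "area_percent") %in% names(areas)))
  if (any(areas$area_percent < 0)) abort("Relative areas must be non-negative")
  total_pct <- sum(areas$area_percent)
  if (abs(total_pct - 100) > 1) {
    abort(sprintf("Relative areas must sum to ~100%% (got %.2f)", total_pct))
  }
  out <- dplyr::mutate(dplyr::arrange(areas, .data$load),
                       dar_contribution = .data$area_percent * .data$load / 100)
  out <- out[c("load", "area_percent", "dar_contribution")]
  structure(out, class = c("dar_report", class(out)),
            total_dar = sum(out$dar_contribution))
}

#' @export
print.dar_report <- function(x, ...) {
  cat("<dar_report> total DAR =", format(round(attr(x, "total_dar"), 2), nsmall = 2), "\n")
  NextMethod()
}

#' Replicate statistics for DAR reports
#'
#' Computes per-load mean relative areas, relative standard deviations
#' (sample sd / mean, in percent) and mean DAR contributions across replicate
#' injections, plus the total-DAR RSD.
#'
#' @param reports List of [dar_from_areas()] results with identical load
#'   groupings.
#' @return A tibble of class `dar_replicate_report` with columns `load`,
#'   `area_percent` (mean), `rsd_percent`, `dar_contribution` (mean);
#'   attributes `total_dar`, `total_rsd`, `n_replicates`. With a single
#'   replicate the RSDs are `NA` and a warning is raised.
#' @export
replicate_stats <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 1L)
  loads <- lapply(reports, function(r) r$load)
  if (!all(vapply(loads, identical, logical(1), loads[[1]]))) {
    abort("All replicates must share the same load grouping")
  }
  n <- length(reports)
  if (n < 2L) {
    warning("Single replicate: RSDs are undefined", call. = FALSE)
  }
  areas <- do.call(cbind, lapply(reports, function(r) r$area_percent))
  totals <- vapply(reports, function(r) attr(r, "total_dar"), numeric(1))
  rsd <- function(v) if (length(v) < 2L) NA_real_ else 100 * sd(v) / mean(v)
  out <- tibble(
    load = loads[[1]],
    area_percent = rowMeans(areas),
    rsd_percent = apply(areas, 1, rsd),
    dar_contribution = rowMeans(areas) * loads[[1]] / 100
  )
  structure(out, class = c("dar_replicate_report", class(out)),
            total_dar = mean(totals), total_rsd = rsd(totals),
            n_replicates = n)
}

#' @export
print.dar_replicate_report <- function(x, ...) {
  cat("<dar_replicate_report> n =", attr(x, "n_replicates"),
      "| total DAR =", format(round(attr(x, "total_dar"), 2), nsmall = 2),
      "| RSD % =",
      ifelse(is.na(attr(x, "total_rsd")), "n/a",
             format(round(attr(x, "total_rsd"), 2), nsmall = 2)), "\n")
  NextMethod()
}

#' Extract a heart-cut fraction from a chromatogram
#'
#' A heart-cut transfers the effluent between `window_start` and
#' `window_end`; the transferred volume is the window width times the flow
#' rate. A purge delay trims the composition window at both ends (the purge
#' flushes residual salt, so material inside the delay is not transferred to
#' the second dimension). When the per-species Gaussian component profiles
#' are known (simulation), the fractional composition of the cut is computed
#' analytically from the species areas inside the trimmed window.
#'
#' @param chrom A [as_chromatogram()] object.
#' @param window_start,window_end Cut window in minutes.
#' @param flow_rate First-dimension flow rate in mL/min.
#' @param purge_delay Purge delay in minutes applied at each end.
#' @param species_profiles Optional tibble with columns `species`,
#'   `apex_time`, `sd`, `area` describing the Gaussian components.
#' @return A list of class `heart_cut` with elements `window_start`,
#'   `window_end`, `flow_rate`, `purge_delay`, `volume_ml`, `fraction_area`
#'   (chromatogram area inside the trimmed window) and `composition` (tibble
#'   `species`, `share`; empty when no species profiles are supplied or the
#'   trimmed window is empty).
#' @examples
#' tm <- seq(0, 10, by = 1 / 1200)
#' chrom <- as_chromatogram(data.frame(time = tm, intensity = dnorm(tm, 5, 0.1)))
#' hc <- extract_heart_cut(chrom, 5.0, 5.2, flow_rate = 0.5)
#' hc$volume_ml # 0.100
#' @export
extract_heart_cut <- function(chrom, window_start, window_end,
                              flow_rate = 0.5, purge_delay = 0,
                              species_profiles = NULL) {
  if (!inherits(chrom, "chromatogram")) chrom <- as_chromatogram(chrom)
  if (window_end < window_start) abort("window_end must be >= window_start")
  if (window_start < min(chrom$time) || window_end > max(chrom$time)) {
    abort("Heart-cut window lies outside the chromatogram time span")
  }
  volume <- (window_end - window_start) * flow_rate
  s <- window_start + purge_delay
  e <- window_end - purge_delay
  empty <- e <= s
  fraction_area <- 0
  if (!empty) {
    idx <- which(chrom$time >= s & chrom$time <= e)
    if (length(idx) >= 2L) {
      fraction_area <- .trapz(chrom$time, chrom$intensity, min(idx), max(idx))
    }
  }
  composition <- tibble(species = character(0), share = numeric(0))
  if (!empty && !is.null(species_profiles)) {
    sp <- as_tibble(species_profiles)
    w <- sp$area * (pnorm((e - sp$apex_time) / sp$sd) -
                    pnorm((s - sp$apex_time) / sp$sd))
    if (sum(w) > 0) {
      composition <- tibble(species = sp$species, share = w / sum(w))
    }
  }
  structure(
    list(window_start = window_start, window_end = window_end,
         flow_rate = flow_rate, purge_delay = purge_delay,
         volume_ml = volume, fraction_area = fraction_area,
         composition = composition),
    class = "heart_cut"
  )
}

#' @export
print.heart_cut <- function(x, ...) {
  cat(sprintf("<heart_cut> %.2f-%.2f min @ %.3f mL/min -> %.3f mL\n",
              x$window_start, x$window_end, x$flow_rate, x$volume_ml))
  if (nrow(x$composition) > 0) print(x$composition)
  invisible(x)
}
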