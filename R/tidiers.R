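# broom-style tidiers for the package's result objects.

#' Tidy a DAR report
#'
#' @param x A `dar_report` (from [dar_from_areas()]).
#' @param ... Unused.
#' @return A tibble with one row per drug load.
#' @export
tidy.dar_report <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @rdname tidy.dar_report
#' @export
glance.dar_report <- function(x, ...) {
  tibble(total_dar = attr(x, "total_dar"), n_loads = nrow(x))
}

#' Tidy a replicate DAR report
#'
#' @param x A `dar_replicate_report` (from [replicate_stats()]).
#' @param ... Unused.
#' @return A tibble with one row per drug load (mean area, RSD,
#'   contribution).
#' @export
tidy.dar_replicate_report <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @rdname tidy.dar_replicate_report
#' @export
glance.dar_replicate_report <- function(x, ...) {
  tibble(total_dar = attr(x, "total_dar"),
         total_rsd = attr(x, "total_rsd"),
         n_replicates = attr(x, "n_replicates"))
}

#' Tidy a peak table
#'
#' @param x A `peak_table` (from [detect_peaks()]).
#' @param ... Unused.
#' @return A plain tibble of the integrated peaks.
#' @export
tidy.peak_table <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @rdname tidy.peak_table
#' @export
glance.peak_table <- function(x, ...) {
  tibble(n_peaks = nrow(x), total_area = attr(x, "total_area"),
         baseline = attr(x, "baseline"))
}

#' Tidy an isoform assignment
#'
#' @param x An `adc_assignment` (from [match_observed()]).
#' @param ... Unused.
#' @return The ranked candidate tibble with per-candidate match counts.
#' @export
tidy.adc_assignment <- function(x, ...) {
  dplyr::select(x$candidates, -"matches")
}

#' @rdname tidy.adc_assignment
#' @export
glance.adc_assignment <- function(x, ...) {
  tibble(best = x$best, unique = x$unique,
         n_observed = length(x$observed))
}

#' Tidy a deconvolution result
#'
#' @param x A `deconvolved_masses` (from [deconvolve()]).
#' @param ... Unused.
#' @return A tibble with `neutral_mass`, `score`, `n_charges`.
#' @export
tidy.deconvolved_masses <- function(x, ...) {
  as_tibble(as.data.frame(x[c("neutral_mass", "score", "n_charges")]))
}

#' Tidy a pipeline report
#'
#' @param x An `adc_report` (from [run_pipeline()]).
#' @param ... Unused.
#' @return The per-load DAR table joined with nothing else; see
#'   `x$assignments` for the per-peak assignments.
#' @export
tidy.adc_report <- function(x, ...) {
  tidy(x$dar)
}

#' @rdname tidy.adc_report
#' @export
glance.adc_report <- function(x, ...) {
  dplyr::bind_cols(tibble(batch = x$batch), glance(x$dar))
}
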