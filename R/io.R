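# Plain-text I/O: two-column CSVs for chromatograms and spectra (with
# comment-line metadata headers), report writers, optional mzML reading.

#' Write / read a chromatogram as two-column CSV
#'
#' The file holds `time_min,intensity_au` with `#`-prefixed metadata lines
#' (wavelength, sampling rate, batch, replicate) at the top.
#'
#' @param chrom A [as_chromatogram()] object.
#' @param path Output file.
#' @return `write_chromatogram_csv()`: the path, invisibly;
#'   `read_chromatogram_csv()`: a `chromatogram` tibble.
#' @export
write_chromatogram_csv <- function(chrom, path) {
  md <- attr(chrom, "metadata") %||% list()
  header <- c(
    sprintf("# wavelength_nm: %s", md$wavelength_nm %||% NA),
    sprintf("# sampling_rate_hz: %s", md$sampling_rate_hz %||% NA),
    sprintf("# batch: %s", md$batch %||% NA),
    sprintf("# replicate: %s", md$replicate %||% NA)
  )
  writeLines(c(header, "time_min,intensity_au"), path)
  readr::write_csv(
    tibble(time_min = chrom$time, intensity_au = chrom$intensity),
    path, append = TRUE)
  invisible(path)
}

#' @rdname write_chromatogram_csv
#' @export
read_chromatogram_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key, cast = identity) {
    line <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(line) == 0L) return(NA)
    v <- trimws(sub(paste0("^# ", key, ":"), "", line[1]))
    if (v == "NA") NA else cast(v)
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  as_chromatogram(
    tibble(time = df$time_min, intensity = df$intensity_au),
    wavelength_nm = get_meta("wavelength_nm", as.numeric),
    sampling_rate_hz = get_meta("sampling_rate_hz", as.numeric),
    batch = get_meta("batch"),
    replicate = get_meta("replicate", as.integer)
  )
}

#' Write / read a continuum mass spectrum as two-column CSV
#'
#' @param spec A [as_mass_spectrum()] object.
#' @param path File path.
#' @return `write_spectrum_csv()`: the path, invisibly;
#'   `read_spectrum_csv()`: a `mass_spectrum` tibble.
#' @export
write_spectrum_csv <- function(spec, path) {
  rng <- attr(spec, "mz_range") %||% range(spec$mz)
  writeLines(c(sprintf("# mz_range: %g %g", rng[1], rng[2]),
               "mz,intensity"), path)
  readr::write_csv(tibble(mz = spec$mz, intensity = spec$intensity),
                   path, append = TRUE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  hdr <- readLines(path, n = 2)
  rng_line <- grep("^# mz_range:", hdr, value = TRUE)
  rng <- if (length(rng_line) > 0) {
    as.numeric(strsplit(trimws(sub("^# mz_range:", "", rng_line[1])), " +")[[1]])
  } else {
    NULL
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  as_mass_spectrum(df, mz_range = rng %||% range(df$mz))
}

#' Read a single continuum MS1 scan from an mzML file
#'
#' Optional convenience reader built on Bioconductor's mzR; the package's
#' primary spectrum format is two-column CSV.
#'
#' @param path Path to an mzML file.
#' @param scan Scan number (default 1).
#' @param mz_range Acquisition window to record on the spectrum.
#' @return A `mass_spectrum` tibble.
#' @export
read_spectrum_mzml <- function(path, scan = 1L, mz_range = c(500, 4000)) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("mzML reading requires the mzR package")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  pk <- mzR::peaks(handle, scan)
  as_mass_spectrum(tibble(mz = pk[, 1], intensity = pk[, 2]),
                   mz_range = mz_range)
}

#' Write an integrated peak table as CSV
#'
#' @param peaks A [detect_peaks()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_peak_csv <- function(peaks, path) {
  df <- as_tibble(as.data.frame(peaks))
  df$area <- signif(df$area, 6)
  df$relative_area <- round(df$relative_area, 2)
  readr::write_csv(df, path)
  invisible(path)
}

#' Write a DAR report (single or replicate) as CSV
#'
#' Mirrors the standard per-load reporting layout: one row per drug load
#' with relative area, RSD and DAR contribution, then a total row.
#'
#' @param report A `dar_report` or `dar_replicate_report`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_dar_csv <- function(report, path) {
  df <- tibble(
    load = as.character(report$load),
    area_percent = round(report$area_percent, 2),
    rsd_percent = if ("rsd_percent" %in% names(report)) {
      round(report$rsd_percent, 2)
    } else {
      NA_real_
    },
    dar_contribution = round(report$dar_contribution, 2)
  )
  total <- tibble(load = "total", area_percent = 100,
                  rsd_percent = round(attr(report, "total_rsd") %||% NA_real_, 2),
                  dar_contribution = round(attr(report, "total_dar"), 2))
  readr::write_csv(dplyr::bind_rows(df, total), path)
  invisible(path)
}

#' Write the signature library as CSV
#'
#' @param assembly An [adc_assembly()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_signature_csv <- function(assembly, path) {
  readr::write_csv(signature_table(assembly), path)
  invisible(path)
}
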