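# Synthetic-data generators: HIC batch chromatograms with known area
# structure, continuum ESI envelopes of dissociated sub-units, and complete
# batch datasets with a ground-truth manifest.
#
# The generators emulate the *measured* statistical structure of the study
# system (relative areas, replicate jitter, envelope geometry), not the
# physics of retention or ionization. Ground truth always travels with the
# data so downstream tests never read truth from the pipeline under test.

# evaluate code under a temporary RNG state (seeded, restored afterwards)
.with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
}

#' Default HIC peak-to-load grouping
#'
#' Peak A is the unconjugated (DAR 0) antibody; B carries DAR 2; C and D are
#' DAR 4 species; E, F and G are DAR 6 species; H is DAR 8. C, E, F and H
#' are MS-confirmed identities; the D and G grouping follows the final drug
#' load distribution assignment.
#'
#' @return Named integer vector mapping peak label to drug load.
#' @export
default_peak_grouping <- function() {
  c(A = 0L, B = 2L, C = 4L, D = 4L, E = 6L, F = 6L, G = 6L, H = 8L)
}

#' Default HIC peak-to-isoform identities used by the simulator
#'
#' C = 4a, E = 6a, F = 6b and H = 8 are the MS-confirmed identities; B, D
#' and G are not identified in the source data, so the simulator assigns the
#' kinetically preferred LC-HC-first products (B = 2a, D = 4b) and reuses 6a
#' for G.
#'
#' @return Named character vector mapping peak label to isoform label.
#' @export
default_peak_isoforms <- function() {
  c(A = "0", B = "2a", C = "4a", D = "4b", E = "6a", F = "6b", G = "6a",
    H = "8")
}

.batch_percents <- list(
  low  = c(`0` = 16.73, `2` = 40.71, `4` = 28.56, `6` = 12.54, `8` = 1.50),
  medium = c(`0` = 2.80, `2` = 18.85, `4` = 41.69, `6` = 26.87, `8` = 9.79),
  high = c(`0` = 0.37, `2` = 3.42, `4` = 30.67, `6` = 28.60, `8` = 36.90)
)

#' HIC batch profile configuration
#'
#' Bundles the 8-peak profile geometry with the per-load target relative
#' areas of one of the three reference drug-load batches. Apex times are
#' simulator conventions; only the elution order (increasing drug load /
#' hydrophobicity) is meaningful. Within-load splits: DAR 4 goes 80:20 to
#' C:D, DAR 6 splits 43.7 / 14.1 / 42.2 across E / F / G.
#'
#' @param batch `"low"`, `"medium"` or `"high"`; or `"custom"` with
#'   `load_percents` supplied.
#' @param load_percents Named vector of per-load percents (names
#'   `0,2,4,6,8`) summing to 100 (+-0.1). Defaults to the selected batch.
#' @param cv_percent Per-peak replicate area coefficient of variation (%).
#' @param noise_sd Baseline noise standard deviation (AU).
#' @param run_minutes,sampling_rate_hz Time grid of the simulated run.
#' @param peak_sd Gaussian peak sd in minutes (all peaks).
#' @param seed Base seed for replicate jitter and noise.
#' @return A list of class `batch_profile_config`.
#' @export
hic_batch_config <- function(batch = c("low", "medium", "high", "custom"),
                             load_percents = NULL, cv_percent = 0.3,
                             noise_sd = 1e-4, run_minutes = 10,
                             sampling_rate_hz = 20, peak_sd = 0.07,
                             seed = 1L) {
  batch <- match.arg(batch)
  if (is.null(load_percents)) {
    if (batch == "custom") abort("custom batch needs load_percents")
    load_percents <- .batch_percents[[batch]]
  }
  if (abs(sum(load_percents) - 100) > 0.1) {
    abort(sprintf("load_percents must sum to 100 (got %.2f)",
                  sum(load_percents)))
  }
  peaks <- tibble(
    label = c("A", "B", "C", "D", "E", "F", "G", "H"),
    apex_time = c(2.0, 3.0, 4.0, 4.5, 5.3, 5.8, 6.3, 7.5),
    sd = peak_sd,
    load = c(0L, 2L, 4L, 4L, 6L, 6L, 6L, 8L),
    fraction = c(1, 1, 0.8, 0.2, 0.437, 0.141, 0.422, 1)
  )
  bad <- tapply(peaks$fraction, peaks$load, function(f) abs(sum(f) - 1) > 1e-6)
  if (any(bad)) abort("Within-load peak fractions must sum to 1")
  structure(
    list(batch = batch, peaks = peaks,
         load_percents = load_percents, cv_percent = cv_percent,
         noise_sd = noise_sd, run_minutes = run_minutes,
         sampling_rate_hz = sampling_rate_hz, seed = seed),
    class = "batch_profile_config"
  )
}

# per-peak true areas (total area 1) after normalizing the percents
.config_peak_areas <- function(config) {
  pct <- config$load_percents / sum(config$load_percents)
  config$peaks$fraction * unname(pct[as.character(config$peaks$load)])
}

#' Ground truth of a batch configuration
#'
#' @param config A [hic_batch_config()].
#' @return List with `peak_areas` (tibble `label`, `load`, `area_percent`),
#'   `load_percents` (normalized, named) and `total_dar`.
#' @export
batch_truth <- function(config) {
  areas <- .config_peak_areas(config)
  loads <- sort(unique(config$peaks$load))
  load_pct <- vapply(loads, function(l) {
    100 * sum(areas[config$peaks$load == l])
  }, numeric(1))
  names(load_pct) <- loads
  list(
    peak_areas = tibble(label = config$peaks$label, load = config$peaks$load,
                        area_percent = 100 * areas),
    load_percents = load_pct,
    total_dar = sum(load_pct * loads) / 100
  )
}

#' Simulate one replicate HIC chromatogram
#'
#' Sum of Gaussian peaks with areas set by the configured per-load percents
#' (split across member peaks by the configured fractions), each multiplied
#' by per-replicate lognormal jitter at the configured CV, plus additive
#' baseline noise. Deterministic for a fixed (config seed, replicate index).
#'
#' @param config A [hic_batch_config()].
#' @param replicate_index Replicate number (1, 2, 3, ...).
#' @return A [as_chromatogram()] tibble; attribute `truth` holds the
#'   jittered per-peak areas actually synthesized.
#' @examples
#' chrom <- make_hic_chromatogram(hic_batch_config("high", cv_percent = 0,
#'                                                 noise_sd = 0))
#' @export
make_hic_chromatogram <- function(config, replicate_index = 1L) {
  stopifnot(inherits(config, "batch_profile_config"))
  dt <- 1 / (config$sampling_rate_hz * 60)
  tm <- seq(0, config$run_minutes, by = dt)
  areas <- .config_peak_areas(config)
  .with_seed(.derive_seed(config$seed, replicate_index), {
    s <- config$cv_percent / 100
    jitter <- if (s > 0) {
      rlnorm(nrow(config$peaks), meanlog = -s^2 / 2, sdlog = s)
    } else {
      rep(1, nrow(config$peaks))
    }
    a <- areas * jitter
    y <- rep(0, length(tm))
    for (i in seq_len(nrow(config$peaks))) {
      y <- y + a[i] * dnorm(tm, config$peaks$apex_time[i], config$peaks$sd[i])
    }
    if (config$noise_sd > 0) y <- y + rnorm(length(tm), 0, config$noise_sd)
    chrom <- as_chromatogram(tibble(time = tm, intensity = y),
                             sampling_rate_hz = config$sampling_rate_hz,
                             batch = config$batch,
                             replicate = replicate_index)
    attr(chrom, "truth") <- tibble(label = config$peaks$label,
                                   load = config$peaks$load, area = a)
    chrom
  })
}

#' ESI envelope generator configuration
#'
#' @param mz_min,mz_max Acquisition window (Th).
#' @param grid_step Continuum grid spacing (Th).
#' @param mass_sd Peak width expressed as mass-domain standard deviation
#'   (Da); the m/z-domain sd of a charge-z peak is `mass_sd / z`. This
#'   models the unresolved isotope/adduct envelope of a large protein.
#' @param noise_rel Additive Gaussian noise sd as a fraction of the envelope
#'   maximum (0 = noise-free).
#' @param seed Seed for the noise draw.
#' @return A list of class `envelope_config`.
#' @export
envelope_config <- function(mz_min = 500, mz_max = 4000, grid_step = 0.025,
                            mass_sd = 6, noise_rel = 0.005, seed = 1L) {
  stopifnot(mz_max > mz_min, grid_step > 0, mass_sd > 0, noise_rel >= 0)
  structure(
    list(mz_min = mz_min, mz_max = mz_max, grid_step = grid_step,
         mass_sd = mass_sd, noise_rel = noise_rel, seed = seed),
    class = "envelope_config"
  )
}

#' Default charge range for a species mass
#'
#' Chosen so the charge envelope falls inside the 500-4,000 Th window:
#' z 15-25 below 30 kDa, z 30-45 below 60 kDa, z 45-60 above (half-antibody
#' and heavy-heavy species).
#'
#' @param mass Neutral mass in Da.
#' @return Integer length-2 charge range.
#' @export
charge_range_for_mass <- function(mass) {
  if (mass < 30000) c(15L, 25L)
  else if (mass < 60000) c(30L, 45L)
  else c(45L, 60L)
}

#' Synthesize a continuum ESI spectrum of one or more species
#'
#' Each species contributes one Gaussian peak per charge state at
#' m/z = (M + z * 1.00728) / z, with per-charge intensities following a
#' discretized bell over the charge range and total intensity proportional
#' to the species weight. Peaks falling outside the acquisition window are
#' suppressed. Additive Gaussian noise (seeded) is applied when configured.
#'
#' @param species Tibble with columns `mass`, `intensity`, and optionally
#'   `z_min`, `z_max` (defaults via [charge_range_for_mass()]).
#' @param config An [envelope_config()].
#' @return A [as_mass_spectrum()] tibble.
#' @export
make_envelope_spectrum <- function(species, config = envelope_config()) {
  species <- as_tibble(species)
  stopifnot(all(c("mass", "intensity") %in% names(species)))
  if (!"z_min" %in% names(species)) {
    zr <- t(vapply(species$mass, charge_range_for_mass, integer(2)))
    species$z_min <- zr[, 1]; species$z_max <- zr[, 2]
  }
  mz <- seq(config$mz_min, config$mz_max, by = config$grid_step)
  y <- rep(0, length(mz))
  for (i in seq_len(nrow(species))) {
    zs <- species$z_min[i]:species$z_max[i]
    zw <- dnorm(zs, mean = mean(zs), sd = max(1, length(zs) / 4))
    zw <- zw / sum(zw)
    for (k in seq_along(zs)) {
      z <- zs[k]
      center <- (species$mass[i] + z * PROTON_MASS) / z
      sd_mz <- config$mass_sd / z
      if (center < config$mz_min - 6 * sd_mz ||
          center > config$mz_max + 6 * sd_mz) next
      lo <- max(1L, floor((center - 6 * sd_mz - config$mz_min) / config$grid_step) + 1L)
      hi <- min(length(mz), ceiling((center + 6 * sd_mz - config$mz_min) / config$grid_step) + 1L)
      idx <- lo:hi
      y[idx] <- y[idx] + species$intensity[i] * zw[k] *
        dnorm(mz[idx], center, sd_mz)
    }
  }
  if (config$noise_rel > 0 && max(y) > 0) {
    y <- .with_seed(config$seed,
                    y + rnorm(length(y), 0, config$noise_rel * max(y)))
  }
  as_mass_spectrum(tibble(mz = mz, intensity = pmax(y, 0)),
                   mz_range = c(config$mz_min, config$mz_max))
}

#' Simulate the heart-cut RP-MS data of one isoform
#'
#' Builds the continuum ESI spectrum of the isoform's dissociated sub-units
#' (one envelope per unique sub-unit, expanded over the heavy-chain
#' glycoform mix) plus a companion second-dimension RP trace with one
#' Gaussian per unique sub-unit, lighter sub-units eluting first. The
#' heavy-heavy sub-unit of isoform 4a additionally carries a dehydration
#' satellite (-18.02 Da) at the configured relative intensity, emulating the
#' water-loss species seen on that fraction.
#'
#' @param isoform Isoform label (e.g. `"8"`, `"6b"`).
#' @param assembly An [adc_assembly()]; defaults to [fixture_igg1()].
#' @param glyco_mix Named weights over heavy-chain glycoforms.
#' @param config An [envelope_config()].
#' @param dehydration_on Character vector of sub-unit compositions that get
#'   a water-loss satellite; default: the two-heavy sub-unit when the
#'   isoform is 4a.
#' @param dehydration_intensity Relative intensity of the satellite.
#' @return List of class `heart_cut_spectrum`: `spectrum`
#'   ([as_mass_spectrum()]), `rp_trace` (tibble `time`, `intensity`),
#'   `truth` (tibble of emitted species masses/weights), `isoform`.
#' @export
make_heart_cut_spectrum <- function(isoform, assembly = fixture_igg1(),
                                    glyco_mix = c(G0F = 0.6, G1F = 0.4),
                                    config = envelope_config(),
                                    dehydration_on = NULL,
                                    dehydration_intensity = 0.25) {
  iso <- enumerate_isoforms(assembly)
  if (!isoform %in% iso$label) {
    abort(paste0("Isoform '", isoform, "' is not in the assembly enumeration"))
  }
  row <- iso[iso$label == isoform, ]
  if (is.null(dehydration_on)) {
    sig0 <- dissociate(row, assembly)
    two_heavy <- sig0$subunit[vapply(sig0$chains, function(ch) {
      sum(vapply(assembly$chains[ch], function(s) s$role, character(1)) == "heavy")
    }, integer(1)) == 2L]
    dehydration_on <- if (isoform == "4a") two_heavy else character(0)
  }

  glyco_names <- names(glyco_mix)
  species <- purrr::map_dfr(seq_along(glyco_mix), function(gi) {
    sig <- dissociate(row, assembly, glycoform = glyco_names[gi])
    tibble(subunit = sig$subunit, mass = sig$mass,
           n_copies = sig$n_copies,
           has_heavy = !is.na(sig$glycoform),
           glycoform = ifelse(is.na(sig$glycoform), NA_character_,
                              glyco_names[gi]),
           weight = ifelse(is.na(sig$glycoform) & gi > 1, 0,
                           ifelse(is.na(sig$glycoform), 1, glyco_mix[gi])) *
             sig$n_copies)
  })
  species <- species[species$weight > 0, ]
  # dehydration satellites
  sat <- species[species$subunit %in% dehydration_on, ]
  if (nrow(sat) > 0) {
    sat$mass <- sat$mass - 18.02
    sat$weight <- sat$weight * dehydration_intensity
    sat$glycoform <- paste0(ifelse(is.na(sat$glycoform), "", sat$glycoform),
                            "-H2O")
    species <- dplyr::bind_rows(species, sat)
  }
  spec <- make_envelope_spectrum(
    tibble(mass = species$mass, intensity = species$weight), config)

  # companion RP trace: one Gaussian per unique sub-unit, light first
  base <- species[!grepl("-H2O$", species$glycoform) | is.na(species$glycoform), ]
  sub_mass <- tapply(base$mass, base$subunit, min)
  ord <- order(sub_mass)
  rt <- 14 + 2 * seq_along(ord) # min, inside the 12-27 min acquisition window
  w <- tapply(base$weight, base$subunit, sum)[ord]
  tm <- seq(12, 27, by = 1 / 60)
  ry <- rep(0, length(tm))
  for (k in seq_along(ord)) {
    ry <- ry + w[k] * dnorm(tm, rt[k], 0.15)
  }
  structure(
    list(spectrum = spec,
         rp_trace = tibble(time = tm, intensity = ry),
         truth = as_tibble(species), isoform = isoform),
    class = "heart_cut_spectrum"
  )
}

#' Generate a complete batch dataset on disk
#'
#' Writes triplicate HIC chromatograms, one heart-cut spectrum per HIC peak
#' (A-H) and a JSON ground-truth manifest, so the whole pipeline can run
#' from files alone.
#'
#' @param batch `"low"`, `"medium"` or `"high"`.
#' @param seed Base seed.
#' @param out_dir Output directory (created if needed).
#' @param n_replicates Number of replicate chromatograms.
#' @param cv_percent,noise_sd,noise_rel Noise settings passed through to the
#'   generators.
#' @return Invisibly, the manifest as a list. Files: `chromatogram_repN.csv`,
#'   `heartcut_<label>.csv`, `rp_trace_<label>.csv`, `manifest.json`.
#' @export
make_batch_dataset <- function(batch, seed = 1L, out_dir,
                               n_replicates = 3L, cv_percent = 0.3,
                               noise_sd = 1e-4, noise_rel = 0.005) {
  if (!batch %in% names(.batch_percents)) {
    abort(paste0("Unknown batch '", batch, "'; expected one of: ",
                 paste(names(.batch_percents), collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- hic_batch_config(batch, cv_percent = cv_percent,
                             noise_sd = noise_sd, seed = seed)
  truth <- batch_truth(config)
  asm <- fixture_igg1()
  iso_map <- default_peak_isoforms()

  chrom_files <- character(n_replicates)
  for (r in seq_len(n_replicates)) {
    chrom <- make_hic_chromatogram(config, replicate_index = r)
    chrom_files[r] <- file.path(out_dir, sprintf("chromatogram_rep%d.csv", r))
    write_chromatogram_csv(chrom, chrom_files[r])
  }

  peak_records <- list()
  for (i in seq_along(iso_map)) {
    lab <- names(iso_map)[i]
    hc <- make_heart_cut_spectrum(
      iso_map[[lab]], assembly = asm,
      config = envelope_config(noise_rel = noise_rel,
                               seed = .derive_seed(seed, 100 + i)))
    spec_file <- file.path(out_dir, sprintf("heartcut_%s.csv", lab))
    write_spectrum_csv(hc$spectrum, spec_file)
    rp_file <- file.path(out_dir, sprintf("rp_trace_%s.csv", lab))
    readr::write_csv(hc$rp_trace, rp_file)
    sig <- dissociate(iso_map[[lab]], asm)
    peak_records[[lab]] <- list(
      label = lab, isoform = unname(iso_map[[lab]]),
      load = unname(default_peak_grouping()[[lab]]),
      true_area_percent = truth$peak_areas$area_percent[
        truth$peak_areas$label == lab],
      true_masses = round(attr(sig, "unique_masses"), 1),
      spectrum_file = basename(spec_file),
      rp_trace_file = basename(rp_file)
    )
  }
  manifest <- list(
    batch = batch, seed = seed, n_replicates = n_replicates,
    cv_percent = cv_percent, noise_sd = noise_sd, noise_rel = noise_rel,
    load_percents = as.list(truth$load_percents),
    total_dar = truth$total_dar,
    chromatograms = basename(chrom_files),
    peaks = peak_records
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
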