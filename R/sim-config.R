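#' Simulation configuration
#'
#' Builds a validated configuration for the polar-growth lineage simulator.
#' The model is a rod-shaped cell that elongates only from its poles, at a
#' constant rate per pole per frame, and divides when it first reaches a
#' length threshold -- the regime described for *Mycobacterium smegmatis*,
#' where the established ("old") pole grows faster than the pole formed at
#' the previous division (the "new" pole).
#'
#' Defaults emulate *M. smegmatis* in a microfluidic device imaged every
#' 15 minutes with a 60x objective (0.11 um pixels): birth at ~2.5 um,
#' division at ~5 um, total elongation ~0.19 um/frame of which ~70% is
#' inserted at the old pole.
#'
#' @param rate_old,rate_new Elongation rate at the old / new pole
#'   (um per frame). Both must be >= 0.
#' @param birth_length,division_length Founder birth length and the division
#'   length threshold (um); `division_length > birth_length`.
#' @param septum_rel_position_mean,septum_rel_position_sd Mean and sd of the
#'   relative septum position, measured from the new pole as a fraction of
#'   cell length; draws are truncated to (0.2, 0.8).
#' @param frame_interval_min Minutes between frames (bookkeeping only; all
#'   rates are per frame).
#' @param pixel_size_um Pixel size (um) used to rasterise axial profiles.
#' @param localization_mode One of `"old_pole"`, `"new_pole"`, `"bipolar"`,
#'   `"midcell_late"`, `"uniform"`: the fluorescence program rendered along
#'   the cell axis.
#' @param septal_onset_fraction Cell-cycle fraction at which septal
#'   relocalization begins (for `"midcell_late"`, and for polar modes when
#'   `septal_transfer_fraction > 0`).
#' @param septal_transfer_fraction Fraction of polar signal moved to the
#'   septum after onset.
#' @param amplitude Spot amplitude (intensity units) at the primary pole
#'   (old pole for `"old_pole"`/`"bipolar"`, new pole for `"new_pole"`,
#'   septum for `"midcell_late"`, everywhere for `"uniform"`).
#' @param secondary_amplitude Amplitude of the new-pole spot in
#'   `"bipolar"` mode.
#' @param spot_sigma_px Gaussian spot sigma, in pixels.
#' @param label_level Intensity of pulse-chase-labeled cell wall.
#' @param noise_sd Gaussian intensity noise sd added to every profile sample.
#' @param background Background intensity added to every profile sample.
#' @param psf_sigma_px Gaussian point-spread sigma (pixels) for rendered
#'   frame images.
#' @param cell_radius_um Rod radius (um) for rendered frame images.
#' @param n_founders Number of founder cells.
#' @param n_generations Lineage depth; founders are generation 1.
#' @param seed Integer seed; fully determines all stochastic draws.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(rate_old = 0.2, rate_new = 0.1, seed = 7)
#' cfg$rate_old / (cfg$rate_old + cfg$rate_new) # old-pole share 2/3
#' @export
sim_config <- function(rate_old = 0.13,
                       rate_new = 0.06,
                       birth_length = 2.5,
                       division_length = 5,
                       septum_rel_position_mean = 0.5,
                       septum_rel_position_sd = 0.05,
                       frame_interval_min = 15,
                       pixel_size_um = 0.11,
                       localization_mode = "old_pole",
                       septal_onset_fraction = 0.75,
                       septal_transfer_fraction = 0,
                       amplitude = 100,
                       secondary_amplitude = 40,
                       spot_sigma_px = 2,
                       label_level = 100,
                       noise_sd = 0,
                       background = 10,
                       psf_sigma_px = 1,
                       cell_radius_um = 0.25,
                       n_founders = 8,
                       n_generations = 3,
                       seed = 1L) {
  cfg <- list(
    rate_old = rate_old, rate_new = rate_new,
    birth_length = birth_length, division_length = division_length,
    septum_rel_position_mean = septum_rel_position_mean,
    septum_rel_position_sd = septum_rel_position_sd,
    frame_interval_min = frame_interval_min,
    pixel_size_um = pixel_size_um,
    localization_mode = localization_mode,
    septal_onset_fraction = septal_onset_fraction,
    septal_transfer_fraction = septal_transfer_fraction,
    amplitude = amplitude, secondary_amplitude = secondary_amplitude,
    spot_sigma_px = spot_sigma_px, label_level = label_level,
    noise_sd = noise_sd, background = background,
    psf_sigma_px = psf_sigma_px, cell_radius_um = cell_radius_um,
    n_founders = n_founders, n_generations = n_generations,
    seed = as.integer(seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  stopifnot_scalar_number(cfg$rate_old, "rate_old", lo = 0)
  stopifnot_scalar_number(cfg$rate_new, "rate_new", lo = 0)
  stopifnot_scalar_number(cfg$birth_length, "birth_length", lo = 1e-9)
  stopifnot_scalar_number(cfg$division_length, "division_length", lo = 1e-9)
  if (cfg$division_length <= cfg$birth_length) {
    abort("`division_length` must exceed `birth_length`",
          class = "polegrow_config_error")
  }
  stopifnot_scalar_number(cfg$septum_rel_position_mean,
                          "septum_rel_position_mean", lo = 1e-9, hi = 1 - 1e-9)
  stopifnot_scalar_number(cfg$septum_rel_position_sd,
                          "septum_rel_position_sd", lo = 0)
  stopifnot_scalar_number(cfg$pixel_size_um, "pixel_size_um", lo = 1e-9)
  for (f in c("septal_onset_fraction", "septal_transfer_fraction")) {
    stopifnot_scalar_number(cfg[[f]], f, lo = 0, hi = 1)
  }
  stopifnot_scalar_number(cfg$noise_sd, "noise_sd", lo = 0)
  stopifnot_scalar_number(cfg$n_founders, "n_founders", lo = 1)
  stopifnot_scalar_number(cfg$n_generations, "n_generations", lo = 1)
  modes <- c("old_pole", "new_pole", "bipolar", "midcell_late", "uniform")
  if (!is.character(cfg$localization_mode) ||
      length(cfg$localization_mode) != 1 ||
      !cfg$localization_mode %in% modes) {
    abort(paste0("`localization_mode` must be one of: ",
                 paste(modes, collapse = ", ")),
          class = "polegrow_config_error")
  }
  if (cfg$rate_old + cfg$rate_new <= 0 && cfg$n_generations > 1) {
    abort("total elongation rate is 0: no cell can reach the division length, so `n_generations` must be 1",
          class = "polegrow_config_error")
  }
  cfg
}

#' Read a simulation configuration from a JSON file
#'
#' Flat key-value JSON; every key must be a `sim_config()` argument --
#' unknown keys are rejected rather than silently ignored.
#'
#' @param path Path to a JSON file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(extra, collapse = ", ")),
          class = "polegrow_config_error")
  }
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  share <- x$rate_old / (x$rate_old + x$rate_new)
  cat("<sim_config>\n")
  cat(sprintf("  elongation: %.3f um/frame (old-pole share %.2f)\n",
              x$rate_old + x$rate_new, share))
  cat(sprintf("  birth %.2f um -> division %.2f um; septum %.2f +/- %.2f\n",
              x$birth_length, x$division_length,
              x$septum_rel_position_mean, x$septum_rel_position_sd))
  cat(sprintf("  localization: %s; noise_sd %.2f; background %.1f\n",
              x$localization_mode, x$noise_sd, x$background))
  cat(sprintf("  %d founder(s) x %d generation(s); seed %d\n",
              x$n_founders, x$n_generations, x$seed))
  invisible(x)
}
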