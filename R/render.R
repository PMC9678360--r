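#' Render the fluorescence-localization track of one simulated cell
#'
#' Produces one axial intensity profile per frame of the cell's life (birth
#' to the last frame before division), rasterised at one sample per pixel.
#' Signal is placed according to `config$localization_mode`:
#' terminal Gaussian spots for the polar modes, a mid-cell spot appearing
#' once the cell-cycle fraction passes `septal_onset_fraction` for
#' `"midcell_late"` (and, when `septal_transfer_fraction > 0`, for the polar
#' modes, with that fraction of the polar amplitude moved to the future
#' septum position), and a flat level for `"uniform"`. Gaussian noise of sd
#' `noise_sd` is added on top of `background`, last.
#'
#' @param record One lineage row (see [simulate_lineage()]).
#' @param config The [sim_config()] the lineage was generated with.
#' @param frame_of_reference `"new_to_old"` (default; index 0 = new pole) or
#'   `"lab"` (left-to-right channel coordinates, orientation unresolved --
#'   what a measurement of raw images would yield).
#' @return A tibble with columns `cell_id`, `frame`, `sample_index`
#'   (0-based), `intensity`, `orientation` (`"new_to_old"` or `"unknown"`).
#' @export
render_localization_track <- function(record, config,
                                      frame_of_reference = c("new_to_old", "lab")) {
  frame_of_reference <- match.arg(frame_of_reference)
  config <- validate_sim_config(config)
  stopifnot(nrow(record) == 1)
  lengths <- record$length_series[[1]]
  n_frames <- length(lengths)
  # track covers birth .. last frame before division
  track_frames <- if (is.na(record$division_frame)) n_frames else n_frames - 1L
  if (track_frames < 1) abort("record has no renderable frames")

  profiles <- purrr::map(seq_len(track_frames), function(i) {
    tau <- if (track_frames > 1) (i - 1) / track_frames else 0
    n_px <- max(2L, as.integer(round(lengths[i] / config$pixel_size_um)))
    base <- localization_signal(n_px, tau, record$truth_septum_rel, config)
    if (frame_of_reference == "lab" && record$new_pole_side == "right") {
      base <- rev(base)
    }
    intensity <- base + config$background
    if (config$noise_sd > 0) {
      intensity <- intensity + rnorm(n_px, 0, config$noise_sd)
    }
    tibble(
      cell_id = record$cell_id, frame = record$birth_frame + i - 1L,
      sample_index = seq_len(n_px) - 1L, intensity = intensity,
      orientation = if (frame_of_reference == "lab") "unknown" else "new_to_old"
    )
  })
  dplyr::bind_rows(profiles)
}

# noise-free signal component in new->old coordinates (index 0 = new pole)
localization_signal <- function(n_px, tau, septum_rel, config) {
  amp <- config$amplitude
  sig <- config$spot_sigma_px
  after_onset <- tau >= config$septal_onset_fraction
  transfer <- if (after_onset) config$septal_transfer_fraction else 0
  septum_center <- if (is.na(septum_rel)) 0.5 * (n_px - 1) else septum_rel * (n_px - 1)

  base <- numeric(n_px)
  mode <- config$localization_mode
  if (mode == "uniform") {
    base <- rep(amp, n_px)
  } else if (mode == "midcell_late") {
    if (after_onset) base <- gaussian_spot(n_px, septum_center, amp, sig)
  } else {
    polar <- switch(mode,
      old_pole = gaussian_spot(n_px, n_px - 1, amp * (1 - transfer), sig),
      new_pole = gaussian_spot(n_px, 0, amp * (1 - transfer), sig),
      bipolar = gaussian_spot(n_px, n_px - 1, amp * (1 - transfer), sig) +
        gaussian_spot(n_px, 0, config$secondary_amplitude, sig)
    )
    base <- polar
    if (transfer > 0) {
      base <- base + gaussian_spot(n_px, septum_center, amp * transfer, sig)
    }
  }
  base
}

#' Render localization tracks for every cell of a lineage
#'
#' @inheritParams render_localization_track
#' @param lineage A `polegrow_lineage` tibble.
#' @return One long profile tibble (see [render_localization_track()]).
#' @export
render_cohort_tracks <- function(lineage, config,
                                 frame_of_reference = c("new_to_old", "lab")) {
  frame_of_reference <- match.arg(frame_of_reference)
  purrr::map_dfr(seq_len(nrow(lineage)), function(i) {
    render_localization_track(lineage[i, ], config, frame_of_reference)
  })
}

#' Render a pulse-chase profile pair for one simulated cell
#'
#' Emulates an amine-reactive-dye pulse chase: at birth the whole cell wall
#' is labeled (bright); by the frame before division the labeled material is
#' flanked by dim, newly inserted wall whose extent at each pole equals the
#' recorded per-pole growth. Profiles are oriented new pole -> old pole;
#' noise is added last.
#'
#' @param record One lineage row.
#' @param config The [sim_config()] used; `label_level` must exceed
#'   `background`, otherwise the label boundary is undetectable by
#'   construction and a configuration error is raised.
#' @param offset_px Unlabeled margin (pixels, >= 0) already present at each
#'   pole at birth, i.e. growth accrued between staining and the first
#'   frame. Default 0.
#' @return A tibble with columns `cell_id`, `stage` (`"birth"` /
#'   `"predivision"`), `sample_index`, `intensity`, `orientation`.
#' @export
render_pulse_chase_pair <- function(record, config, offset_px = 0) {
  config <- validate_sim_config(config)
  stopifnot(nrow(record) == 1)
  if (offset_px < 0) {
    abort("`offset_px` must be >= 0", class = "polegrow_config_error")
  }
  if (config$label_level <= config$background) {
    abort("`label_level` must exceed `background`: the label boundary would be undetectable",
          class = "polegrow_config_error")
  }
  if (length(record$length_series[[1]]) < 2) {
    abort("record must span at least 2 frames")
  }
  px <- config$pixel_size_um
  n_birth <- max(2L, as.integer(round(record$birth_length_um / px)))
  g_new <- as.integer(round(record$truth_growth_new_um / px))
  g_old <- as.integer(round(record$truth_growth_old_um / px))
  n_pre <- n_birth + g_new + g_old

  label_profile <- function(n, margin_new, margin_old) {
    v <- rep(config$background, n)
    lo <- margin_new + 1L
    hi <- n - margin_old
    if (lo <= hi) v[lo:hi] <- config$label_level
    if (config$noise_sd > 0) v <- v + rnorm(n, 0, config$noise_sd)
    v
  }
  offset_px <- as.integer(round(offset_px))
  dplyr::bind_rows(
    tibble(cell_id = record$cell_id, stage = "birth",
           sample_index = seq_len(n_birth) - 1L,
           intensity = label_profile(n_birth, offset_px, offset_px),
           orientation = "new_to_old"),
    tibble(cell_id = record$cell_id, stage = "predivision",
           sample_index = seq_len(n_pre) - 1L,
           intensity = label_profile(n_pre, offset_px + g_new, offset_px + g_old),
           orientation = "new_to_old")
  )
}

#' Render pulse-chase pairs for every cell of a lineage
#'
#' @inheritParams render_pulse_chase_pair
#' @param lineage A `polegrow_lineage` tibble.
#' @return One long tibble of stacked pairs.
#' @export
render_pulse_chase_cohort <- function(lineage, config, offset_px = 0) {
  purrr::map_dfr(seq_len(nrow(lineage)), function(i) {
    render_pulse_chase_pair(lineage[i, ], config, offset_px)
  })
}
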