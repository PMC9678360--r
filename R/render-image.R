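#' Render a toy microscopy frame for the cells alive at one timepoint
#'
#' Draws each live cell as a horizontal spherocylinder intensity footprint
#' (phase channel) carrying its axial localization signal (fluorescence
#' channel), convolves both with an isotropic Gaussian PSF of sigma
#' `config$psf_sigma_px`, and emits the ground-truth label mask. Cells are
#' placed at random non-overlapping positions (with a retry budget), away
#' from the border so segmentation and flux checks are well-posed. This is
#' a deliberately simple stand-in for real micrographs: no photobleaching,
#' flow artifacts, or focus drift.
#'
#' @param lineage A `polegrow_lineage`.
#' @param frame Frame index to render.
#' @param config The [sim_config()] used for the lineage.
#' @param phase_level Footprint intensity of the phase channel.
#' @param margin_px Border margin kept clear of cells.
#' @param max_retries Placement attempts per cell before giving up.
#' @return A list with numeric matrices `phase` and `fluor`, integer matrix
#'   `mask` (0 = background), and a `placements` tibble (`cell_id`, `label`,
#'   `row`, `col_start`, `length_px`, `flipped`).
#' @export
render_frame_image <- function(lineage, frame, config, phase_level = 100,
                               margin_px = 6, max_retries = 100) {
  config <- validate_sim_config(config)
  alive <- dplyr::filter(
    as_tibble(lineage),
    .data$birth_frame <= frame,
    (is.na(.data$division_frame) &
       frame < .data$birth_frame + lengths(.data$length_series)) |
      (!is.na(.data$division_frame) & frame < .data$division_frame)
  )
  px <- config$pixel_size_um
  r_px <- max(1L, as.integer(round(config$cell_radius_um / px)))

  lens_px <- if (nrow(alive) > 0) {
    vapply(seq_len(nrow(alive)), function(i) {
      ls <- alive$length_series[[i]]
      max(2L, as.integer(round(ls[frame - alive$birth_frame[i] + 1] / px)))
    }, integer(1))
  } else integer(0)

  height <- max(64L, (nrow(alive) + 1) * (4 * r_px + 2 * margin_px))
  width <- max(64L, max(c(0L, lens_px)) + 6 * margin_px)
  phase <- matrix(config$background, height, width)
  fluor <- matrix(0, height, width)
  mask <- matrix(0L, height, width)
  occupied <- matrix(FALSE, height, width)
  placements <- NULL

  for (i in seq_len(nrow(alive))) {
    rec <- alive[i, ]
    n_px <- lens_px[i]
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      row <- floor(runif(1, margin_px + r_px + 1, height - margin_px - r_px))
      col <- floor(runif(1, margin_px + 1, width - margin_px - n_px))
      rows <- (row - r_px - 1):(row + r_px + 1)
      cols <- (col - 1):(col + n_px)
      rows <- rows[rows >= 1 & rows <= height]
      cols <- cols[cols >= 1 & cols <= width]
      if (!any(occupied[rows, cols])) {
        occupied[rows, cols] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf("could not place cell %s without overlap at frame %d",
                    rec$cell_id, frame),
            class = "polegrow_placement_error")
    }

    tau_frames <- if (is.na(rec$division_frame)) {
      length(rec$length_series[[1]])
    } else rec$division_frame - rec$birth_frame
    tau <- if (tau_frames > 1) (frame - rec$birth_frame) / tau_frames else 0
    signal <- localization_signal(n_px, tau, rec$truth_septum_rel, config)
    flipped <- rec$new_pole_side == "right"
    if (flipped) signal <- rev(signal)

    # spherocylinder footprint: distance to the axis segment <= r
    ax_lo <- col + r_px
    ax_hi <- col + n_px - 1 - r_px
    for (rr in (row - r_px):(row + r_px)) {
      for (cc in col:(col + n_px - 1)) {
        cx <- pmin(pmax(cc, ax_lo), ax_hi)
        if ((rr - row)^2 + (cc - cx)^2 <= r_px^2) {
          mask[rr, cc] <- i
          phase[rr, cc] <- phase[rr, cc] + phase_level
          fluor[rr, cc] <- fluor[rr, cc] + signal[pmin(n_px, pmax(1, cc - col + 1))]
        }
      }
    }
    placements <- dplyr::bind_rows(placements, tibble(
      cell_id = rec$cell_id, label = i, row = row, col_start = col,
      length_px = n_px, flipped = flipped
    ))
  }

  if (config$psf_sigma_px > 0) {
    rlang::check_installed("EBImage", reason = "for PSF convolution")
    phase <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(phase), sigma = config$psf_sigma_px)))
    fluor <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(fluor), sigma = config$psf_sigma_px)))
  }
  if (config$noise_sd > 0) {
    phase <- phase + matrix(rnorm(length(phase), 0, config$noise_sd),
                            nrow(phase))
    fluor <- fluor + matrix(rnorm(length(fluor), 0, config$noise_sd),
                            nrow(fluor))
  }
  list(phase = phase, fluor = fluor, mask = mask,
       placements = placements %||% tibble())
}
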