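#' Orient a single axial profile by its brightest pole
#'
#' Compares the mean intensity of the leading vs trailing
#' `ceiling(terminal_fraction * length)` samples and flips the profile so
#' the brighter terminal region sits at index 0. An exact tie keeps the
#' original order.
#'
#' @param samples Numeric vector of intensities along the cell axis.
#' @param terminal_fraction Fraction of the profile length treated as the
#'   pole region; must lie in (0, 0.5].
#' @return The (possibly reversed) sample vector, with attribute `flipped`.
#' @examples
#' orient_by_brightest_pole(c(1, 1, 5), 1 / 3) # -> 5 1 1
#' @export
orient_by_brightest_pole <- function(samples, terminal_fraction = 0.1) {
  if (terminal_fraction <= 0 || terminal_fraction > 0.5) {
    abort("`terminal_fraction` must lie in (0, 0.5]",
          class = "polegrow_config_error")
  }
  tm <- terminal_means(samples, terminal_fraction)
  flipped <- tm["trail"] > tm["lead"]
  out <- if (flipped) rev(samples) else samples
  attr(out, "flipped") <- unname(flipped)
  out
}

#' Orient every profile of a table by its brightest pole
#'
#' Table verb applying [orient_by_brightest_pole()] per profile (grouped by
#' `cell_id` and, when present, `frame`/`stage`).
#'
#' @param profiles Long profile tibble with `cell_id`, `sample_index`,
#'   `intensity` (optionally `frame` or `stage`).
#' @param terminal_fraction See [orient_by_brightest_pole()].
#' @return The profile tibble with `sample_index` re-ordered per profile and
#'   `orientation` set to `"brightest_left"`.
#' @export
orient_profiles_brightest <- function(profiles, terminal_fraction = 0.1) {
  keys <- intersect(c("cell_id", "frame", "stage"), names(profiles))
  profiles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$sample_index, .by_group = TRUE) |>
    dplyr::mutate(
      intensity = as.numeric(orient_by_brightest_pole(.data$intensity,
                                                      terminal_fraction)),
      orientation = "brightest_left"
    ) |>
    dplyr::ungroup()
}

#' Resolve new-pole/old-pole orientation of tracks from the lineage
#'
#' Assigns pole identity to measured profiles using the recorded division
#' geometry: the daughter end that coincides with the mother's septum
#' position (within a tolerance of half the mother's division length) is the
#' new pole, and the whole track is flipped so that sample index 0 is the
#' new pole. Founder cells have no recorded division, so their orientation
#' stays `"unknown"`; downstream pole-resolved operations skip them.
#'
#' @param profiles Long lab-frame profile tibble (`cell_id`, `frame`,
#'   `sample_index`, `intensity`, `orientation`).
#' @param lineage The `polegrow_lineage` the cells belong to.
#' @param tolerance_um Matching tolerance for the septum position; default
#'   half the mother's division length.
#' @return The profile tibble with consistent per-cell flips applied and
#'   `orientation` set to `"new_to_old"` for resolved cells.
#' @export
orient_track_new_to_old <- function(profiles, lineage, tolerance_um = NULL) {
  flips <- resolve_new_pole_side(lineage, tolerance_um)
  profiles |>
    dplyr::left_join(flips, by = "cell_id") |>
    dplyr::group_by(.data$cell_id, .data$frame) |>
    dplyr::mutate(
      sample_index = dplyr::if_else(
        rep(isTRUE(.data$flip[1]), dplyr::n()),
        max(.data$sample_index) - .data$sample_index,
        .data$sample_index),
      orientation = dplyr::if_else(rep(is.na(.data$flip[1]), dplyr::n()),
                                   "unknown", "new_to_old")
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"flip") |>
    dplyr::arrange(.data$cell_id, .data$frame, .data$sample_index)
}

# per cell: flip = TRUE if the lab-frame left end is the old pole
# (i.e. new pole on the right); NA for founders (orientation unknowable)
resolve_new_pole_side <- function(lineage, tolerance_um = NULL) {
  lin <- as_tibble(lineage)
  mothers <- lin[match(lin$mother_id, lin$cell_id), ]
  septum_x <- ifelse(
    mothers$new_pole_side == "left",
    mothers$x_left_div_um + mothers$truth_septum_rel * mothers$division_length_um,
    mothers$x_right_div_um - mothers$truth_septum_rel * mothers$division_length_um
  )
  tol <- tolerance_um %||% (mothers$division_length_um / 2)
  x_left <- lin$x_left_birth_um
  x_right <- lin$x_left_birth_um + lin$birth_length_um
  left_is_septum <- abs(x_left - septum_x) < tol
  right_is_septum <- abs(x_right - septum_x) < tol
  flip <- rep(NA, nrow(lin))
  ok <- !lin$founder & !is.na(septum_x)
  unresolved <- ok & !(left_is_septum | right_is_septum)
  if (any(unresolved)) {
    abort(paste0("cannot resolve pole identity for cell(s): ",
                 paste(lin$cell_id[unresolved], collapse = ", "),
                 " (neither end matches the mother's septum position)"),
          class = "polegrow_lineage_error")
  }
  # if both ends fall within tolerance, the nearer one wins
  d_left <- abs(x_left - septum_x)
  d_right <- abs(x_right - septum_x)
  flip[ok] <- d_right[ok] < d_left[ok]
  tibble(cell_id = lin$cell_id, flip = flip)
}

#' Segment a single-channel image into labeled cells
#'
#' Global Otsu threshold followed by connected-component labeling.
#' Components touching the image border, or smaller than `min_area` pixels,
#' are discarded. Intended for clean synthetic frames, not for crowded real
#' micrographs.
#'
#' @param image Numeric matrix (one channel).
#' @param min_area Minimum component area in pixels.
#' @param discard_border Drop components touching the image border
#'   (default TRUE).
#' @return An integer label matrix (0 = background), relabeled 1..n.
#' @export
segment_frame <- function(image, min_area = 20, discard_border = TRUE) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix", class = "polegrow_format_error")
  }
  rlang::check_installed("EBImage", reason = "for image segmentation")
  rng <- range(image)
  if (diff(rng) == 0) {
    return(matrix(0L, nrow(image), ncol(image))) # constant image: no objects
  }
  scaled <- (image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled))
  labels <- EBImage::imageData(EBImage::bwlabel(scaled > thr))
  labels <- matrix(as.integer(labels), nrow(image), ncol(image))

  keep <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (discard_border && length(keep) > 0) {
    border <- unique(c(labels[1, ], labels[nrow(labels), ],
                       labels[, 1], labels[, ncol(labels)]))
    dropped <- intersect(keep, border)
    if (length(dropped) > 0) {
      warn(sprintf("discarded %d component(s) touching the image border",
                   length(dropped)))
      keep <- setdiff(keep, border)
    }
  }
  areas <- tabulate(labels[labels > 0], nbins = max(labels, 1))
  keep <- keep[areas[keep] >= min_area]

  out <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  out
}

#' Extract an axial intensity profile along a cell's medial axis
#'
#' Computes the medial axis of one segmented object (morphological thinning,
#' pruned to the longest geodesic path, extended tangentially to the object
#' boundary at both tips), then samples the image at 1-pixel steps along it,
#' averaging the intensity across `width_px` perpendicular to the local axis
#' direction -- the automated equivalent of a hand-drawn segmented-line
#' profile of the configured width. Samples falling outside the image are
#' excluded from the perpendicular average.
#'
#' @param image Numeric matrix.
#' @param mask Logical (or 0/1) matrix of the same dimensions marking one
#'   object.
#' @param width_px Odd integer width (pixels) of the averaging band;
#'   the conventional choices are 5 for localization profiles and 7 for
#'   pulse-chase profiles.
#' @return A tibble with `sample_index` (0-based) and `intensity`;
#'   orientation is unknown (no pole identity is implied).
#' @export
extract_axial_profile <- function(image, mask, width_px = 5) {
  if (width_px < 1 || width_px %% 2 == 0) {
    abort("`width_px` must be an odd integer >= 1",
          class = "polegrow_config_error")
  }
  mask <- mask > 0
  if (!any(mask)) abort("`mask` is empty", class = "polegrow_precondition_error")
  if (!identical(dim(image), dim(mask))) {
    abort("`image` and `mask` dimensions differ", class = "polegrow_format_error")
  }
  path <- medial_axis_path(mask)
  half <- (width_px - 1) / 2
  n <- nrow(path)
  intensity <- vapply(seq_len(n), function(i) {
    # local tangent from neighbouring path points
    i0 <- max(1, i - 2)
    i1 <- min(n, i + 2)
    tangent <- c(path[i1, 1] - path[i0, 1], path[i1, 2] - path[i0, 2])
    tangent <- tangent / sqrt(sum(tangent^2))
    normal <- c(-tangent[2], tangent[1])
    offs <- seq(-half, half)
    vals <- vapply(offs, function(o) {
      bilinear_sample(image, path[i, 1] + o * normal[1],
                      path[i, 2] + o * normal[2])
    }, numeric(1))
    mean(vals[!is.na(vals)])
  }, numeric(1))
  tibble(sample_index = seq_len(n) - 1L, intensity = intensity)
}

# bilinear interpolation at (row, col), 1-based continuous coordinates;
# NA outside the image
bilinear_sample <- function(image, r, c) {
  nr <- nrow(image)
  nc <- ncol(image)
  if (r < 1 || r > nr || c < 1 || c > nc) return(NA_real_)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- min(r0 + 1, nr); c1 <- min(c0 + 1, nc)
  fr <- r - r0; fc <- c - c0
  (1 - fr) * (1 - fc) * image[r0, c0] + (1 - fr) * fc * image[r0, c1] +
    fr * (1 - fc) * image[r1, c0] + fr * fc * image[r1, c1]
}
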