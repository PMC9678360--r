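#' Measure per-pole growth from a pulse-chase profile pair
#'
#' Quantifies how much unlabeled (new) cell wall was inserted at each pole
#' between birth and the frame before division. In each profile the labeled
#' region is the maximal contiguous run of samples at or above a threshold
#' `theta = background + threshold_fraction * (plateau - background)`, where
#' the labeled-plateau level is estimated as the median of the top quartile
#' of samples. The unlabeled margin at a pole is the distance (pixels) from
#' the cell end to the nearest labeled-region boundary; growth at that pole
#' is the margin increase from birth to pre-division, floored at 0.
#'
#' Multiple above-threshold runs separated by more than `gap_px` yield the
#' `ambiguous_label` QC flag (the longest run is used); a floor that clips
#' more than 1 px of negative margin change yields `floored_negative`.
#'
#' @param birth,predivision Numeric intensity vectors (or tibbles with an
#'   `intensity` column ordered by `sample_index`), both oriented
#'   new pole -> old pole.
#' @param threshold_fraction Fraction of the plateau-minus-background range
#'   defining the label boundary; in (0, 1), default 0.5 (half-plateau).
#' @param background Background intensity level (default 0).
#' @param pixel_size_um Pixel size for unit conversion (default 1, i.e.
#'   report pixels).
#' @param gap_px Largest between-run gap still merged silently.
#' @param cell_id Optional identifier carried into the result.
#' @return A one-row tibble: `cell_id`, `growth_new_um`, `growth_old_um`,
#'   `elongation_um`, `qc_flags` (comma-separated, `""` if clean).
#' @examples
#' birth <- rep(100, 20)
#' prediv <- c(rep(0, 6), rep(100, 20), rep(0, 4))
#' measure_polar_growth(birth, prediv) # new 6 px, old 4 px
#' @export
measure_polar_growth <- function(birth, predivision, threshold_fraction = 0.5,
                                 background = 0, pixel_size_um = 1,
                                 gap_px = 2, cell_id = NA_character_) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    abort("`threshold_fraction` must lie in (0, 1)",
          class = "polegrow_config_error")
  }
  as_samples <- function(x) {
    if (is.data.frame(x)) {
      if ("sample_index" %in% names(x)) x <- x[order(x$sample_index), ]
      x <- x$intensity
    }
    as.numeric(x)
  }
  b <- as_samples(birth)
  p <- as_samples(predivision)

  mb <- labeled_margins(b, threshold_fraction, background, gap_px, cell_id)
  mp <- labeled_margins(p, threshold_fraction, background, gap_px, cell_id)

  d_new <- mp$margin_new - mb$margin_new
  d_old <- mp$margin_old - mb$margin_old
  flags <- unique(c(mb$flags, mp$flags))
  if (d_new < -1 || d_old < -1) flags <- c(flags, "floored_negative")
  tibble(
    cell_id = cell_id,
    growth_new_um = max(0, d_new) * pixel_size_um,
    growth_old_um = max(0, d_old) * pixel_size_um,
    elongation_um = (length(p) - length(b)) * pixel_size_um,
    qc_flags = paste(flags, collapse = ",")
  )
}

# margins (px) of the labeled region from each end of one profile
labeled_margins <- function(samples, threshold_fraction, background, gap_px,
                            cell_id) {
  n <- length(samples)
  top <- sort(samples, decreasing = TRUE)[seq_len(max(1, ceiling(n / 4)))]
  plateau <- median(top)
  theta <- background + threshold_fraction * (plateau - background)
  above <- samples >= theta
  if (plateau <= background || !any(above)) {
    abort(sprintf("no labeled region found (cell %s): no sample reaches the threshold",
                  cell_id),
          class = "polegrow_no_labeled_region")
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  flags <- character(0)
  if (length(runs) > 1) {
    gaps <- starts[runs][-1] - ends[runs][-length(runs)] - 1
    if (any(gaps > gap_px)) {
      flags <- "ambiguous_label"
      best <- runs[which.max(r$lengths[runs])]
    } else {
      best <- NULL # merge: take span from first to last run
    }
  } else {
    best <- runs
  }
  if (is.null(best)) {
    lo <- starts[runs[1]]
    hi <- ends[runs[length(runs)]]
  } else {
    lo <- starts[best]
    hi <- ends[best]
  }
  list(margin_new = lo - 1, margin_old = n - hi, flags = flags)
}

#' Measure polar growth for a cohort of pulse-chase pairs
#'
#' Applies [measure_polar_growth()] to every cell of a stacked pair table
#' (as produced by [render_pulse_chase_cohort()]), carrying through any
#' `strain` / `replicate` labels, and appends the asymmetry index and the
#' old-pole share of growth.
#'
#' @param pairs Long tibble with `cell_id`, `stage`
#'   (`"birth"`/`"predivision"`), `sample_index`, `intensity`, and
#'   optionally `strain`, `replicate`.
#' @inheritParams measure_polar_growth
#' @return A tibble, one row per cell, with growth columns, `share_old`
#'   (growth_old / total), `asymmetry`, and `qc_flags`.
#' @export
measure_polar_growth_cohort <- function(pairs, threshold_fraction = 0.5,
                                        background = 0, pixel_size_um = 1,
                                        gap_px = 2) {
  labels <- intersect(c("strain", "replicate"), names(pairs))
  pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("cell_id", labels)))) |>
    dplyr::group_map(function(g, key) {
      m <- measure_polar_growth(
        g[g$stage == "birth", ], g[g$stage == "predivision", ],
        threshold_fraction, background, pixel_size_um, gap_px,
        cell_id = key$cell_id
      )
      dplyr::bind_cols(key[setdiff(names(key), "cell_id")], m)
    }) |>
    dplyr::bind_rows() |>
    asymmetry_index()
}

#' Per-cell polar-growth asymmetry index
#'
#' Adds `share_old = growth_old / (growth_old + growth_new)` and the
#' asymmetry index `a = (growth_old - growth_new) / (growth_old +
#' growth_new)`, which is 0 for symmetric growth and +/-1 for purely
#' unipolar growth. Cells with zero total polar growth get `NA` and the
#' `zero_growth` QC flag instead of a crash.
#'
#' @param measurements Tibble with `growth_old_um` and `growth_new_um`
#'   columns (e.g. from [measure_polar_growth_cohort()]).
#' @return The tibble with `share_old` and `asymmetry` columns appended.
#' @export
asymmetry_index <- function(measurements) {
  if (!"qc_flags" %in% names(measurements)) measurements$qc_flags <- ""
  total <- measurements$growth_old_um + measurements$growth_new_um
  zero <- total <= 0
  measurements |>
    dplyr::mutate(
      share_old = dplyr::if_else(zero, NA_real_, .data$growth_old_um / total),
      asymmetry = dplyr::if_else(
        zero, NA_real_,
        (.data$growth_old_um - .data$growth_new_um) / total),
      qc_flags = dplyr::if_else(
        zero,
        ifelse(.data$qc_flags == "", "zero_growth",
               paste0(.data$qc_flags, ",zero_growth")),
        .data$qc_flags)
    )
}
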