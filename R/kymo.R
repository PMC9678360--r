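#' Interpolate one cell's track onto a common cell-cycle by length grid
#'
#' Builds the per-cell kymograph: each frame's axial profile is linearly
#' resampled to `L` bins over relative position 0 (new pole) to 1 (old
#' pole), and the resulting rows -- at relative cycle times `i/(F-1)` for
#' `F` frames -- are linearly resampled along time to `T` bins over
#' \[0, 1\]. Bilinear interpolation overall, no extrapolation: grid
#' endpoints map exactly onto the first/last frame and the pole tips.
#'
#' @param track Long profile tibble for one cell (columns `cell_id`,
#'   `frame`, `sample_index`, `intensity`, `orientation`), oriented
#'   `"new_to_old"`, with at least 2 frames of at least 2 samples each.
#' @param T_bins,L_bins Number of time and position bins (>= 2); the
#'   defaults (50 x 100) give 1% positional bins and oversample a
#'   multi-hour cell cycle imaged every 15 minutes.
#' @return A `kymograph`: a `T_bins x L_bins` numeric matrix with
#'   attributes `cell_id` and `normalization = "none"`. Rows are cycle-time
#'   bins (0 -> 1), columns position bins (new pole -> old pole).
#' @examples
#' tr <- tibble::tibble(
#'   cell_id = "c1", frame = rep(0:1, each = 2),
#'   sample_index = rep(0:1, 2), intensity = c(0, 2, 2, 4),
#'   orientation = "new_to_old"
#' )
#' grid_normalize_track(tr, T_bins = 3, L_bins = 3)
#' @export
grid_normalize_track <- function(track, T_bins = 50, L_bins = 100) {
  if (T_bins < 2 || L_bins < 2) {
    abort("`T_bins` and `L_bins` must be >= 2", class = "polegrow_config_error")
  }
  if (length(unique(track$cell_id)) != 1) {
    abort("`track` must contain exactly one cell")
  }
  if (any(track$orientation != "new_to_old")) {
    abort("track orientation must be resolved new_to_old before gridding",
          class = "polegrow_orientation_error")
  }
  frames <- sort(unique(track$frame))
  if (length(frames) < 2) {
    abort("track must span at least 2 frames",
          class = "polegrow_precondition_error")
  }
  pos_grid <- seq(0, 1, length.out = L_bins)
  rows <- vapply(frames, function(f) {
    p <- track[track$frame == f, ]
    p <- p[order(p$sample_index), ]
    if (nrow(p) < 2) {
      abort("each frame profile needs at least 2 samples",
            class = "polegrow_precondition_error")
    }
    x <- (p$sample_index - min(p$sample_index)) /
      (max(p$sample_index) - min(p$sample_index))
    approx(x, p$intensity, xout = pos_grid)$y
  }, numeric(L_bins))
  # rows: L_bins x F; interpolate along time onto T_bins
  t_src <- seq(0, 1, length.out = length(frames))
  t_grid <- seq(0, 1, length.out = T_bins)
  values <- t(apply(rows, 1, function(col) approx(t_src, col, xout = t_grid)$y))
  values <- t(values) # T_bins x L_bins
  new_kymograph(values, cell_id = track$cell_id[1], normalization = "none")
}

new_kymograph <- function(values, cell_id = NA_character_,
                          normalization = "none", n_cells = NULL,
                          cell_ids = NULL) {
  structure(values,
            cell_id = cell_id, normalization = normalization,
            n_cells = n_cells, cell_ids = cell_ids,
            class = if (is.null(n_cells)) "kymograph" else
              c("avg_kymograph", "kymograph"))
}

normalize_kymograph <- function(values, normalization) {
  switch(normalization,
    none = values,
    row_sum = {
      s <- rowSums(values)
      if (any(s == 0)) {
        abort("row_sum normalization undefined: a time-row sums to 0")
      }
      sweep(values, 1, s, "/")
    },
    global_max = {
      m <- max(values)
      if (m == 0) abort("global_max normalization undefined: all-zero kymograph")
      values / m
    },
    abort(sprintf("unknown normalization mode '%s'", normalization),
          class = "polegrow_config_error")
  )
}

#' Average kymographs across a cohort of cells
#'
#' Each kymograph is first normalized per the chosen mode, then the
#' pointwise arithmetic mean is taken across cells. With the default
#' `"row_sum"` mode every time-row of every cell is scaled to sum 1, so the
#' average reads as the probability of finding the fluorescent protein at a
#' given relative position at a given cell-cycle stage. `"global_max"` and
#' `"none"` are retained for raw intensity comparisons across strains.
#'
#' @param kymos A non-empty list of `kymograph` objects sharing grid shape.
#' @param normalization `"row_sum"` (default), `"global_max"`, or `"none"`.
#' @return An `avg_kymograph` (matrix with `n_cells`, `cell_ids`,
#'   `normalization` attributes).
#' @export
average_kymographs <- function(kymos, normalization = c("row_sum", "global_max", "none")) {
  normalization <- match.arg(normalization)
  if (length(kymos) == 0) {
    abort("`kymos` must be non-empty", class = "polegrow_precondition_error")
  }
  dims <- unique(lapply(kymos, dim))
  if (length(dims) != 1) {
    abort("all kymographs must share the same T x L grid",
          class = "polegrow_shape_error")
  }
  normed <- lapply(kymos, function(k) normalize_kymograph(unclass(k), normalization))
  mean_vals <- Reduce(`+`, normed) / length(normed)
  new_kymograph(mean_vals, normalization = normalization,
                n_cells = length(kymos),
                cell_ids = vapply(kymos, function(k)
                  attr(k, "cell_id") %||% NA_character_, character(1)))
}

#' Build per-cell kymographs for every cell of a profile table
#'
#' @param profiles Long profile tibble oriented `"new_to_old"` (cells with
#'   other orientations are dropped with a warning).
#' @inheritParams grid_normalize_track
#' @return A named list of `kymograph` objects, one per cell.
#' @export
kymographs_from_profiles <- function(profiles, T_bins = 50, L_bins = 100) {
  unresolved <- unique(profiles$cell_id[profiles$orientation != "new_to_old"])
  if (length(unresolved) > 0) {
    warn(sprintf("dropping %d cell(s) with unresolved orientation",
                 length(unresolved)))
    profiles <- profiles[!profiles$cell_id %in% unresolved, ]
  }
  ids <- unique(profiles$cell_id)
  setNames(lapply(ids, function(id) {
    grid_normalize_track(profiles[profiles$cell_id == id, ], T_bins, L_bins)
  }), ids)
}

#' Per-cell pole intensities at a single cell-cycle timepoint
#'
#' For each cell's kymograph, takes the time-row nearest `cycle_fraction`
#' and reports the mean intensity of the first `ceiling(pole_window * L)`
#' position bins (new pole) and of the last as many bins (old pole) -- the
#' single-timepoint contrast used to compare old-pole accumulation across
#' strains.
#'
#' @param kymos Non-empty list of `kymograph` objects.
#' @param cycle_fraction Relative cell-cycle time in \[0, 1\].
#' @param pole_window Fraction of the cell length treated as the pole
#'   region, in (0, 0.5].
#' @return A tibble with `cell_id`, `new_pole_intensity`,
#'   `old_pole_intensity`.
#' @export
pole_intensity_snapshot <- function(kymos, cycle_fraction = 0.25, pole_window = 0.1) {
  if (length(kymos) == 0) {
    abort("`kymos` must be non-empty", class = "polegrow_precondition_error")
  }
  stopifnot_scalar_number(cycle_fraction, "cycle_fraction", 0, 1)
  stopifnot_scalar_number(pole_window, "pole_window", 1e-12, 0.5)
  purrr::imap_dfr(kymos, function(k, id) {
    v <- unclass(k)
    times <- seq(0, 1, length.out = nrow(v))
    row <- v[which.min(abs(times - cycle_fraction)), ]
    w <- ceiling(pole_window * length(row))
    tibble(
      cell_id = if (is.null(attr(k, "cell_id")) || is.na(attr(k, "cell_id")))
        as.character(id) else attr(k, "cell_id"),
      new_pole_intensity = mean(row[seq_len(w)]),
      old_pole_intensity = mean(row[seq(length(row) - w + 1, length(row))])
    )
  })
}

#' @export
print.kymograph <- function(x, ...) {
  n <- attr(x, "n_cells")
  cat(sprintf("<%s> %d time bins x %d position bins; normalization: %s\n",
              if (is.null(n)) "kymograph" else
                sprintf("avg_kymograph of %d cells", n),
              nrow(x), ncol(x), attr(x, "normalization")))
  invisible(x)
}

#' @method tidy kymograph
#' @export
tidy.kymograph <- function(x, ...) {
  v <- unclass(x)
  attributes(v) <- list(dim = dim(v))
  tidyr::expand_grid(
    time = seq(0, 1, length.out = nrow(v)),
    position = seq(0, 1, length.out = ncol(v))
  ) |>
    dplyr::mutate(intensity = as.vector(t(v)))
}
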