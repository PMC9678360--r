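#' Build a demograph from single-timepoint axial profiles
#'
#' Stacks per-cell axial intensity profiles into a population snapshot:
#' each profile is oriented so its brightest pole is at index 0
#' ([orient_by_brightest_pole()]), rows are left-aligned at that pole and
#' right-padded with `NA`, then sorted by ascending cell length -- length
#' serving as a proxy for cell-cycle progression. The sort is stable, so
#' input order is preserved among equal lengths. Profiles keep their
#' absolute length: no length normalization is applied, since that would
#' hide the length-ordering signal.
#'
#' @param profiles Long profile tibble (`cell_id`, `sample_index`,
#'   `intensity`); one profile per cell.
#' @param terminal_fraction Pole window used for the brightest-pole
#'   comparison (default 0.1).
#' @return A `demograph`: a cells x position matrix (NA-padded) with
#'   attributes `lengths_px` (per-row profile length), `cell_ids`,
#'   `alignment_side = "left"`. Rows are ordered shortest first.
#' @examples
#' pr <- tibble::tibble(
#'   cell_id = rep(c("a", "b"), each = 3),
#'   sample_index = rep(0:2, 2),
#'   intensity = c(5, 1, 1, 1, 1, 5)
#' )
#' d <- build_demograph(pr)
#' d[, 1] # both rows start at their bright pole
#' @export
build_demograph <- function(profiles, terminal_fraction = 0.1) {
  if (nrow(profiles) == 0) {
    abort("`profiles` must be non-empty", class = "polegrow_precondition_error")
  }
  split_profiles <- profiles |>
    dplyr::arrange(.data$sample_index) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_split()
  # preserve input (first-appearance) order for stable tie-breaking
  first_seen <- match(unique(profiles$cell_id),
                      vapply(split_profiles, function(p) p$cell_id[1], character(1)))
  split_profiles <- split_profiles[first_seen]

  oriented <- lapply(split_profiles, function(p) {
    as.numeric(orient_by_brightest_pole(p$intensity, terminal_fraction))
  })
  ids <- vapply(split_profiles, function(p) p$cell_id[1], character(1))
  lens <- lengths(oriented)
  ord <- order(lens) # stable (radix) sort: ties keep input order
  oriented <- oriented[ord]
  ids <- ids[ord]
  lens <- lens[ord]

  width <- max(lens)
  rows <- t(vapply(oriented, function(v) c(v, rep(NA_real_, width - length(v))),
                   numeric(width)))
  structure(rows,
            lengths_px = lens, cell_ids = ids, alignment_side = "left",
            terminal_fraction = terminal_fraction,
            class = c("demograph", class(rows)))
}

#' @export
print.demograph <- function(x, ...) {
  cat(sprintf("<demograph> %d cells, lengths %d-%d px, brightest pole left\n",
              nrow(x), min(attr(x, "lengths_px")), max(attr(x, "lengths_px"))))
  invisible(x)
}

#' @method tidy demograph
#' @export
tidy.demograph <- function(x, ...) {
  v <- unclass(x)
  attributes(v) <- list(dim = dim(v))
  tibble(
    cell_id = rep(attr(x, "cell_ids"), each = ncol(v)),
    rank = rep(seq_len(nrow(v)), each = ncol(v)),
    length_px = rep(attr(x, "lengths_px"), each = ncol(v)),
    sample_index = rep(seq_len(ncol(v)) - 1L, nrow(v)),
    intensity = as.vector(t(v))
  ) |>
    dplyr::filter(!is.na(.data$intensity))
}
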