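# Delimited-text and TIFF IO. Every table is tab-separated with a
# commented header block recording column meaning, conventions (0-based
# sample indices, index 0 = new pole where resolved) and the seed, so each
# file is self-describing and round-trips losslessly.

#' Write a table as tab-separated text with a commented metadata header
#'
#' @param df A data frame.
#' @param path Output path.
#' @param meta Named list written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_polegrow_table <- function(df, path, meta = list()) {
  header <- c(
    "# polegrow table",
    sprintf("# %s: %s", names(meta),
            vapply(meta, function(v) paste(format(v), collapse = ","), character(1)))
  )
  writeLines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a table written by [write_polegrow_table()]
#'
#' @param path Input path.
#' @return A tibble; header metadata is attached as attribute `meta`.
#' @export
read_polegrow_table <- function(path) {
  lines <- readLines(path, n = 50)
  meta_lines <- grep("^# [^:]+: ", lines[startsWith(lines, "#")], value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- sub("^# ", "", l)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]+: ", "", kv)
  }
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  attr(out, "meta") <- meta
  out
}

#' Export a kymograph as a delimited numeric matrix
#'
#' The header block records grid shape, normalization mode and contributing
#' cell ids; the body is a plain `T x L` tab-separated matrix.
#'
#' @param kymo A `kymograph` or `avg_kymograph`.
#' @param path Output path.
#' @param meta Extra header entries (e.g. seed).
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path, meta = list()) {
  meta <- c(list(
    T_bins = nrow(kymo), L_bins = ncol(kymo),
    normalization = attr(kymo, "normalization"),
    n_cells = attr(kymo, "n_cells") %||% 1,
    cell_ids = paste(attr(kymo, "cell_ids") %||% attr(kymo, "cell_id"),
                     collapse = ",")
  ), meta)
  header <- c("# polegrow kymograph",
              sprintf("# %s: %s", names(meta), vapply(meta, function(v)
                paste(format(v), collapse = ","), character(1))))
  writeLines(header, path)
  body <- apply(unclass(kymo), 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t"))
  cat(body, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' Read a kymograph written by [write_kymograph()]
#'
#' @param path Input path.
#' @return A `kymograph` (or `avg_kymograph` if `n_cells > 1`).
#' @export
read_kymograph <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (l in grep("^# [^:]+: ", lines[is_meta], value = TRUE)) {
    kv <- sub("^# ", "", l)
    meta[[sub(":.*$", "", kv)]] <- sub("^[^:]+: ", "", kv)
  }
  vals <- do.call(rbind, lapply(strsplit(lines[!is_meta], "\t"), as.numeric))
  n_cells <- as.integer(meta$n_cells %||% 1)
  ids <- strsplit(meta$cell_ids %||% "", ",")[[1]]
  new_kymograph(vals,
                cell_id = if (n_cells == 1) ids[1] else NA_character_,
                normalization = meta$normalization %||% "none",
                n_cells = if (n_cells > 1) n_cells else NULL,
                cell_ids = if (n_cells > 1) ids else NULL)
}

#' Export a demograph as delimited text
#'
#' One row per cell (shortest first): cell id, length in pixels, then the
#' aligned intensity samples; the NA padding is written as empty fields.
#'
#' @param demo A `demograph`.
#' @param path Output path.
#' @param meta Extra header entries.
#' @return `path`, invisibly.
#' @export
write_demograph <- function(demo, path, meta = list()) {
  df <- tibble(
    cell_id = attr(demo, "cell_ids"),
    length_px = attr(demo, "lengths_px")
  )
  m <- as.data.frame(unclass(demo))
  names(m) <- sprintf("s%04d", seq_len(ncol(m)) - 1)
  write_polegrow_table(
    dplyr::bind_cols(df, m), path,
    meta = c(list(alignment_side = "left",
                  terminal_fraction = attr(demo, "terminal_fraction")), meta)
  )
}

#' Write image frames as a multi-page TIFF (one file per channel)
#'
#' Intensity frames are written as 32-bit float pages. TIFF stores values
#' in \[0, 1\], so pages are min-max scaled with the bounds recorded in a
#' `<path>.scale.json` sidecar; [read_frames_tiff()] undoes the scaling.
#' Label masks should use [write_mask_tiff()].
#'
#' @param frames List of numeric matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(frames, path) {
  rlang::check_installed("tiff", reason = "for TIFF output")
  lo <- min(vapply(frames, min, numeric(1)), 0)
  hi <- max(vapply(frames, max, numeric(1)), lo + 1e-12)
  scaled <- lapply(frames, function(f) (f - lo) / (hi - lo))
  tiff::writeTIFF(scaled, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(list(lo = lo, hi = hi), paste0(path, ".scale.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write integer label masks as a 16-bit multi-page TIFF
#'
#' @param masks List of integer matrices (labels 0..65535).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(masks, path) {
  rlang::check_installed("tiff", reason = "for TIFF output")
  tiff::writeTIFF(lapply(masks, function(m) m / 65535), path,
                  bits.per.sample = 16, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF as a list of matrices
#'
#' @param path Input path.
#' @param as_mask Rescale 16-bit label pages back to integer labels.
#' @return List of numeric (or integer) matrices.
#' @export
read_frames_tiff <- function(path, as_mask = FALSE) {
  rlang::check_installed("tiff", reason = "for TIFF input")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".scale.json")
  scale <- if (!as_mask && file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  lapply(pages, function(p) {
    m <- matrix(as.numeric(p), nrow(p))
    if (as_mask) return(matrix(as.integer(round(m * 65535)), nrow(m)))
    if (!is.null(scale)) m <- m * (scale$hi - scale$lo) + scale$lo
    m
  })
}
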