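# track construction and an independent brute-force bilinear oracle,
# shared by the kymograph unit tests and the acceptance checks

make_track <- function(profiles, cell_id = "c1", frames = NULL) {
  frames <- frames %||% (seq_along(profiles) - 1L)
  dplyr::bind_rows(purrr::map2(profiles, frames, function(p, f) {
    tibble::tibble(cell_id = cell_id, frame = f,
                   sample_index = seq_along(p) - 1L, intensity = p,
                   orientation = "new_to_old")
  }))
}

# independent brute-force bilinear oracle: position pass then time pass,
# computed pointwise from the interpolation formula
oracle_grid <- function(profiles, T_bins, L_bins) {
  interp1 <- function(xs, ys, x) {
    if (x <= xs[1]) return(ys[1])
    if (x >= xs[length(xs)]) return(ys[length(ys)])
    i <- max(which(xs <= x))
    if (xs[i] == x) return(ys[i])
    w <- (x - xs[i]) / (xs[i + 1] - xs[i])
    (1 - w) * ys[i] + w * ys[i + 1]
  }
  F <- length(profiles)
  out <- matrix(NA_real_, T_bins, L_bins)
  for (ti in seq_len(T_bins)) {
    for (li in seq_len(L_bins)) {
      pos <- (li - 1) / (L_bins - 1)
      vals_at_pos <- vapply(profiles, function(p) {
        interp1(seq(0, 1, length.out = length(p)), p, pos)
      }, numeric(1))
      tau <- (ti - 1) / (T_bins - 1)
      out[ti, li] <- interp1(seq(0, 1, length.out = F), vals_at_pos, tau)
    }
  }
  out
}
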