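#' Simulate a lineage of polar-growing cells
#'
#' Grows `n_founders` independent lineages for `n_generations` generations.
#' Each cell elongates by `rate_old + rate_new` um per frame, inserted at
#' the two poles in the configured proportion, and divides at the first
#' frame at which its length reaches `division_length`, placing the septum
#' at a truncated-normal relative position. Each daughter inherits one
#' pre-existing pole (age incremented) and one pole born at the septum
#' (age 1). Founder cells are assigned `old_pole_age = 1` by convention and
#' flagged `founder = TRUE`: without an observed division their new/old
#' pole identity is unknowable, and pole-resolved statistics exclude them.
#'
#' Cells also carry a one-dimensional "lab frame": an interval on a channel
#' axis whose left end moves with the left pole and right end with the
#' right pole, so daughters keep their mother's spatial orientation. This
#' is what pole-orientation recovery (see [orient_track_new_to_old()]) is
#' tested against.
#'
#' @param config A [sim_config()].
#' @return A tibble of class `polegrow_lineage`, one row per cell:
#'   `cell_id`, `mother_id`, `generation`, `founder`, `birth_frame`,
#'   `division_frame` (`NA` for never-dividing cells under zero growth),
#'   `old_pole_age`, `new_pole_side` (`"left"`/`"right"` in the lab frame),
#'   birth/division lengths and lab-frame coordinates, per-pole ground-truth
#'   growth (`truth_growth_old_um`, `truth_growth_new_um`),
#'   `truth_septum_rel` (septum position from the new pole, as a fraction),
#'   and `length_series` (list-column, um per frame from birth to division).
#' @examples
#' lin <- simulate_lineage(sim_config(seed = 1))
#' dplyr::count(lin, generation)
#' @export
simulate_lineage <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  total_rate <- config$rate_old + config$rate_new
  horizon_frames <- 10L # observation window for never-dividing cells

  queue <- vector("list", config$n_founders)
  for (i in seq_len(config$n_founders)) {
    queue[[i]] <- list(
      mother_id = NA_character_, generation = 1L, founder = TRUE,
      birth_frame = 0L, birth_length = config$birth_length,
      old_pole_age = 1L,
      # founder pole identity is physical but unobservable; draw it
      new_pole_side = sample(c("left", "right"), 1),
      x_left_birth = (i - 1) * 50 # well-separated channel origins
    )
  }

  rows <- list()
  next_id <- 1L
  while (length(queue) > 0) {
    cell <- queue[[1]]
    queue <- queue[-1]
    cell_id <- sprintf("c%04d", next_id)
    next_id <- next_id + 1L

    if (total_rate > 0) {
      n_grow <- max(1L, as.integer(ceiling(
        (config$division_length - cell$birth_length) / total_rate - 1e-12)))
      length_series <- cell$birth_length + total_rate * (0:n_grow)
      division_frame <- cell$birth_frame + n_grow
      growth_old <- config$rate_old * n_grow
      growth_new <- config$rate_new * n_grow
      divides <- TRUE
    } else {
      n_grow <- horizon_frames
      length_series <- rep(cell$birth_length, n_grow + 1)
      division_frame <- NA_integer_
      growth_old <- growth_new <- 0
      divides <- FALSE
    }

    div_length <- length_series[length(length_series)]
    growth_left <- if (cell$new_pole_side == "left") growth_new else growth_old
    growth_right <- div_length - cell$birth_length - growth_left
    x_left_div <- cell$x_left_birth - growth_left
    x_right_div <- cell$x_left_birth + cell$birth_length + growth_right

    septum_rel <- rtruncnorm(1, config$septum_rel_position_mean,
                             config$septum_rel_position_sd, 0.2, 0.8)

    rows[[cell_id]] <- tibble(
      cell_id = cell_id, mother_id = cell$mother_id,
      generation = cell$generation, founder = cell$founder,
      birth_frame = cell$birth_frame, division_frame = division_frame,
      old_pole_age = cell$old_pole_age, new_pole_side = cell$new_pole_side,
      birth_length_um = cell$birth_length, division_length_um = div_length,
      x_left_birth_um = cell$x_left_birth,
      x_left_div_um = x_left_div, x_right_div_um = x_right_div,
      truth_growth_old_um = growth_old, truth_growth_new_um = growth_new,
      truth_septum_rel = if (divides) septum_rel else NA_real_,
      length_series = list(length_series)
    )

    if (divides && cell$generation < config$n_generations) {
      # absolute septum position, measured from the mother's new pole
      septum_x <- if (cell$new_pole_side == "left") {
        x_left_div + septum_rel * div_length
      } else {
        x_right_div - septum_rel * div_length
      }
      # left daughter keeps the mother's left pole; its new pole is the septum
      left_old_age <- if (cell$new_pole_side == "left") 2L else cell$old_pole_age + 1L
      right_old_age <- if (cell$new_pole_side == "right") 2L else cell$old_pole_age + 1L
      queue <- c(queue, list(
        list(mother_id = cell_id, generation = cell$generation + 1L,
             founder = FALSE, birth_frame = division_frame,
             birth_length = septum_x - x_left_div, old_pole_age = left_old_age,
             new_pole_side = "right", x_left_birth = x_left_div),
        list(mother_id = cell_id, generation = cell$generation + 1L,
             founder = FALSE, birth_frame = division_frame,
             birth_length = x_right_div - septum_x, old_pole_age = right_old_age,
             new_pole_side = "left", x_left_birth = septum_x)
      ))
    }
  }

  out <- dplyr::bind_rows(rows)
  class(out) <- c("polegrow_lineage", class(out))
  attr(out, "config") <- config
  out
}

#' Simulate a cohort of non-founder cells
#'
#' Convenience wrapper mirroring the standard time-lapse experiment of
#' following N cells from birth to division: simulates lineages (expanding the
#' founder count as needed) and returns the lineage restricted to the first
#' `n_cells` non-founder cells, whose pole identities are known from their
#' recorded division.
#'
#' @param config A [sim_config()].
#' @param n_cells Number of non-founder cells required.
#' @param full Return the complete lineage (founders and ancestors included)
#'   with a logical `in_cohort` column, instead of only the cohort rows.
#'   Orientation recovery needs the mothers, so pipelines use `full = TRUE`.
#' @return A `polegrow_lineage` tibble: `n_cells` non-founder rows, or the
#'   full lineage when `full = TRUE`.
#' @export
simulate_cohort <- function(config, n_cells = 25, full = FALSE) {
  config <- validate_sim_config(config)
  # generations g >= 2 contribute n_founders * (2^(g-1)) cells
  per_founder <- 2^config$n_generations - 2
  if (per_founder < 1) {
    abort("`n_generations` must be >= 2 to obtain non-founder cells",
          class = "polegrow_config_error")
  }
  config$n_founders <- max(config$n_founders, ceiling(n_cells / per_founder))
  lin <- simulate_lineage(config)
  non_founders <- which(!lin$founder)
  if (length(non_founders) < n_cells) {
    abort("simulation produced fewer non-founder cells than requested")
  }
  cohort_ids <- lin$cell_id[non_founders[seq_len(n_cells)]]
  out <- if (full) {
    dplyr::mutate(lin, in_cohort = .data$cell_id %in% cohort_ids)
  } else {
    lin[lin$cell_id %in% cohort_ids, ]
  }
  class(out) <- c("polegrow_lineage", class(out))
  attr(out, "config") <- config
  out
}

#' Lineage table in plain (non-list) form for export
#'
#' Drops the `length_series` list-column and adds the per-cell elongation,
#' giving a flat table writable as delimited text.
#'
#' @param lineage A `polegrow_lineage` tibble.
#' @return A plain tibble.
#' @export
flatten_lineage <- function(lineage) {
  dplyr::mutate(
    dplyr::select(as_tibble(lineage), -"length_series"),
    elongation_um = .data$division_length_um - .data$birth_length_um
  )
}
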