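# shared fixtures: small, fast simulation configs built in code

# clean two-generation config with exact hand-checkable numbers
tiny_config <- function(...) {
  args <- list(
    rate_old = 0.2, rate_new = 0.1, birth_length = 2, division_length = 4,
    septum_rel_position_mean = 0.5, septum_rel_position_sd = 0,
    pixel_size_um = 0.1, noise_sd = 0, background = 0,
    n_founders = 2, n_generations = 2, seed = 42L
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# a lineage record with unit pixels and round-number truths, for
# constructed-geometry pulse-chase tests
manual_record <- function(growth_new = 6, growth_old = 4, birth_px = 20) {
  tibble::tibble(
    cell_id = "m1", mother_id = NA_character_, generation = 1L, founder = FALSE,
    birth_frame = 0L, division_frame = 10L, old_pole_age = 2L,
    new_pole_side = "left",
    birth_length_um = birth_px, division_length_um = birth_px + growth_new + growth_old,
    x_left_birth_um = 0, x_left_div_um = -growth_new,
    x_right_div_um = birth_px + growth_old,
    truth_growth_old_um = growth_old, truth_growth_new_um = growth_new,
    truth_septum_rel = 0.5,
    length_series = list(seq(birth_px, birth_px + growth_new + growth_old,
                             length.out = 11))
  )
}

# per-cell recovered old-pole share for a simulated pulse-chase cohort
recover_shares <- function(config, n_cells) {
  cohort <- simulate_cohort(config, n_cells)
  pairs <- render_pulse_chase_cohort(cohort, config)
  meas <- measure_polar_growth_cohort(
    pairs, background = config$background,
    pixel_size_um = config$pixel_size_um)
  meas$share_old
}

# minimal pipeline config used by pipeline and acceptance tests
small_pipeline_config <- function(seed = 1L, n_cells = 15, n_replicates = 2) {
  pipeline_config(
    strains = list(
      WT = list(rate_old = 0.133, rate_new = 0.057, noise_sd = 5),
      mutant = list(rate_old = 0.095, rate_new = 0.095, noise_sd = 5)
    ),
    n_replicates = n_replicates, n_cells = n_cells, seed = seed,
    grid_t = 20, grid_l = 50, reference_strain = "mutant"
  )
}
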