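test_that("grid interpolation matches the hand-computed 2-frame example", {
  k <- grid_normalize_track(make_track(list(c(0, 2), c(2, 4))), 3, 3)
  expect_equal(unclass(k), matrix(c(0, 1, 2, 1, 2, 3, 2, 3, 4), 3, 3,
                                  byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("grid interpolation is the identity on already-gridded constant tracks", {
  k <- grid_normalize_track(make_track(list(rep(5, 4), rep(5, 4), rep(5, 4))),
                            3, 4)
  expect_true(all(unclass(k) == 5))
})

test_that("grid interpolation agrees with a brute-force bilinear oracle on random tracks", {
  withr::local_seed(100)
  max_err <- 0
  for (i in 1:100) {
    F <- sample(2:20, 1)
    profiles <- purrr::map(seq_len(F), function(f) rnorm(sample(5:200, 1)))
    T_bins <- sample(2:30, 1)
    L_bins <- sample(2:40, 1)
    got <- unclass(grid_normalize_track(make_track(profiles), T_bins, L_bins))
    want <- oracle_grid(profiles, T_bins, L_bins)
    max_err <- max(max_err, max(abs(got - want)))
  }
  expect_lt(max_err, 1e-9)
})

test_that("gridding preconditions are enforced", {
  expect_error(grid_normalize_track(make_track(list(c(1, 2)))),
               class = "polegrow_precondition_error")
  expect_error(grid_normalize_track(make_track(list(c(1, 2), c(1, 2))), 1, 5),
               class = "polegrow_config_error")
  tr <- make_track(list(c(1, 2), c(3, 4)))
  tr$orientation <- "unknown"
  expect_error(grid_normalize_track(tr),
               class = "polegrow_orientation_error")
})

test_that("averaging normalizes per cell then takes the pointwise mean", {
  k2 <- grid_normalize_track(make_track(list(c(2, 2), c(2, 2))), 3, 3)
  k4 <- grid_normalize_track(make_track(list(c(4, 4), c(4, 4))), 3, 3)
  # mode none: midpoint of constants
  avg <- average_kymographs(list(k2, k4), "none")
  expect_true(all(unclass(avg) == 3))
  expect_equal(attr(avg, "n_cells"), 2)
  # single kymograph, mode none: identity
  expect_equal(unclass(average_kymographs(list(k2), "none")), unclass(k2),
               ignore_attr = TRUE)
  # row_sum contract: every row sums to 1
  ka <- grid_normalize_track(make_track(list(c(1, 5, 2), c(2, 1, 9))), 5, 7)
  kb <- grid_normalize_track(make_track(list(c(4, 2), c(1, 3))), 5, 7)
  avg_rs <- average_kymographs(list(ka, kb), "row_sum")
  expect_equal(rowSums(unclass(avg_rs)), rep(1, 5), tolerance = 1e-9)
  # global_max contract
  avg_gm <- average_kymographs(list(ka), "global_max")
  expect_equal(max(unclass(avg_gm)), 1)
  # errors
  expect_error(average_kymographs(list(), "none"),
               class = "polegrow_precondition_error")
  k_other <- grid_normalize_track(make_track(list(c(1, 2), c(3, 4))), 4, 3)
  expect_error(average_kymographs(list(k2, k_other)),
               class = "polegrow_shape_error")
})

test_that("averaging is mirror-equivariant and stays in the per-point envelope", {
  withr::local_seed(7)
  tracks <- purrr::map(1:6, function(i) {
    make_track(purrr::map(1:4, ~ runif(12)), cell_id = paste0("c", i))
  })
  kymos <- purrr::map(tracks, grid_normalize_track, T_bins = 8, L_bins = 15)
  avg <- average_kymographs(kymos, "none")
  flipped <- purrr::map(tracks, function(tr) {
    tr |>
      dplyr::group_by(.data$frame) |>
      dplyr::mutate(sample_index = max(.data$sample_index) - .data$sample_index) |>
      dplyr::ungroup()
  })
  avg_f <- average_kymographs(purrr::map(flipped, grid_normalize_track,
                                         T_bins = 8, L_bins = 15), "none")
  expect_equal(unclass(avg_f), unclass(avg)[, 15:1], ignore_attr = TRUE)

  stack <- simplify2array(purrr::map(kymos, unclass))
  expect_true(all(unclass(avg) >= apply(stack, 1:2, min) - 1e-12))
  expect_true(all(unclass(avg) <= apply(stack, 1:2, max) + 1e-12))
})

test_that("a uniform cohort yields a flat average kymograph", {
  cfg <- tiny_config(localization_mode = "uniform")
  lin <- simulate_lineage(cfg)
  profiles <- render_cohort_tracks(lin, cfg)
  kymos <- kymographs_from_profiles(profiles, 10, 20)
  avg <- average_kymographs(kymos, "none")
  v <- unclass(avg)
  expect_lt(stats::sd(v) / mean(v), 1e-9)
})

test_that("pole snapshots read the expected rows and windows", {
  m <- matrix(0, 5, 20)
  m[, 19:20] <- 1 # signal in the last 10% of positions
  k <- polegrow:::new_kymograph(m, cell_id = "a")
  snap <- pole_intensity_snapshot(list(k), cycle_fraction = 0.5,
                                  pole_window = 0.1)
  expect_equal(snap$old_pole_intensity, 1)
  expect_equal(snap$new_pole_intensity, 0)
  ku <- polegrow:::new_kymograph(matrix(3, 4, 10), cell_id = "b")
  snap_u <- pole_intensity_snapshot(list(ku), 0.25, 0.2)
  expect_equal(snap_u$old_pole_intensity, snap_u$new_pole_intensity)
  expect_error(pole_intensity_snapshot(list()),
               class = "polegrow_precondition_error")
})

test_that("an old-pole cohort shows strong old/new pole contrast at quarter cycle", {
  cfg <- sim_config(localization_mode = "old_pole", noise_sd = 5,
                    n_founders = 4, n_generations = 3, seed = 13)
  cohort <- simulate_cohort(cfg, 25)
  profiles <- render_cohort_tracks(cohort, cfg)
  kymos <- kymographs_from_profiles(profiles)
  snap <- pole_intensity_snapshot(kymos, cycle_fraction = 0.25)
  ratio <- (snap$old_pole_intensity - cfg$background) /
    pmax(snap$new_pole_intensity - cfg$background, 1e-9)
  expect_gt(median(ratio), 2)
})

test_that("kymographs round-trip through the delimited export", {
  k <- grid_normalize_track(make_track(list(c(0.1, 2.3), c(7, 0.5))), 4, 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kymograph(k, path, meta = list(seed = 3))
  back <- read_kymograph(path)
  expect_equal(unclass(back), unclass(k), ignore_attr = TRUE)
  expect_equal(attr(back, "normalization"), "none")
})
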