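test_that("brightest-pole orientation compares terminal means and keeps ties", {
  expect_equal(as.numeric(orient_by_brightest_pole(c(1, 1, 5), 1 / 3)),
               c(5, 1, 1))
  expect_equal(as.numeric(orient_by_brightest_pole(c(5, 1, 1), 1 / 3)),
               c(5, 1, 1))
  expect_equal(as.numeric(orient_by_brightest_pole(c(3, 1, 3), 1 / 3)),
               c(3, 1, 3)) # exact tie: original order kept
  expect_error(orient_by_brightest_pole(c(1, 2), 0.7),
               class = "polegrow_config_error")
})

test_that("orienting twice by the brightest pole is an involution", {
  withr::local_seed(1)
  for (i in 1:20) {
    v <- rnorm(sample(5:40, 1))
    once <- as.numeric(orient_by_brightest_pole(v))
    twice <- as.numeric(orient_by_brightest_pole(once))
    expect_equal(twice, once)
  }
})

test_that("lineage geometry recovers every non-founder's pole orientation", {
  cfg <- sim_config(n_founders = 4, n_generations = 3, seed = 21,
                    septum_rel_position_sd = 0.07)
  lin <- simulate_lineage(cfg)
  flips <- polegrow:::resolve_new_pole_side(lin)
  merged <- dplyr::left_join(flips, lin, by = "cell_id")
  non_f <- merged[!merged$founder, ]
  # flip = TRUE means lab-left end is the old pole, i.e. new pole right
  expect_equal(non_f$flip, non_f$new_pole_side == "right")
  expect_true(all(is.na(merged$flip[merged$founder])))
})

test_that("orientation recovery is robust to shuffled lineage rows (swapped daughters)", {
  cfg <- sim_config(n_founders = 2, n_generations = 3, seed = 8)
  lin <- simulate_lineage(cfg)
  shuffled <- lin[rev(seq_len(nrow(lin))), ]
  flips <- polegrow:::resolve_new_pole_side(shuffled)
  merged <- dplyr::left_join(flips, lin, by = "cell_id")
  non_f <- merged[!merged$founder, ]
  expect_equal(non_f$flip, non_f$new_pole_side == "right")
})

test_that("orient_track_new_to_old flips lab profiles onto the new->old convention", {
  cfg <- tiny_config(localization_mode = "old_pole")
  lin <- simulate_lineage(cfg)
  lab <- render_cohort_tracks(lin, cfg, "lab")
  truth <- render_cohort_tracks(lin, cfg, "new_to_old")
  oriented <- orient_track_new_to_old(lab, lin)
  non_f <- lin$cell_id[!lin$founder]
  for (id in non_f) {
    a <- oriented[oriented$cell_id == id, ]
    b <- truth[truth$cell_id == id, ]
    expect_equal(a$intensity[order(a$frame, a$sample_index)],
                 b$intensity[order(b$frame, b$sample_index)])
    expect_true(all(a$orientation == "new_to_old"))
  }
  expect_true(all(oriented$orientation[oriented$cell_id %in%
                                         lin$cell_id[lin$founder]] == "unknown"))
})

test_that("segmentation finds synthetic rods and applies the stated filters", {
  skip_if_not_installed("EBImage")
  # blank image: no objects
  expect_equal(max(segment_frame(matrix(3, 40, 40))), 0)

  cfg <- tiny_config(localization_mode = "uniform", background = 0)
  lin <- simulate_lineage(cfg)
  withr::local_seed(4)
  img <- render_frame_image(lin[1, , drop = FALSE], 0, cfg)
  seg <- segment_frame(img$phase, min_area = 10)
  expect_equal(max(seg), 1)
  expect_equal(seg > 0, img$mask > 0)

  # rod touching the border is discarded with a warning
  shifted <- img$phase[, colSums(img$mask) > 0, drop = FALSE]
  pad <- cbind(shifted, matrix(0, nrow(shifted), 30))
  expect_warning(seg2 <- segment_frame(pad, min_area = 10), "border")
  expect_equal(max(seg2), 0)
})

test_that("axial profiles along the medial axis reproduce direct row indexing on straight rods", {
  # horizontal rod with a known intensity gradient along its axis
  img <- matrix(0, 21, 60)
  mask <- matrix(FALSE, 21, 60)
  cols <- 10:49
  for (cc in cols) {
    img[9:13, cc] <- cc # constant across the width, varies along the axis
    mask[9:13, cc] <- TRUE
  }
  pr1 <- extract_axial_profile(img, mask, width_px = 1)
  direct <- img[11, cols]
  expect_lte(abs(nrow(pr1) - length(cols)), 3)
  # interior samples match the central row: unit gradient, correct range
  interior <- 5:(nrow(pr1) - 4)
  expect_true(all(abs(diff(pr1$intensity[interior]) - 1) < 1e-6) ||
                all(abs(diff(pr1$intensity[interior]) + 1) < 1e-6))
  expect_true(all(pr1$intensity[interior] >= min(direct) - 1e-6 &
                    pr1$intensity[interior] <= max(direct) + 1e-6))

  # uniform rod: any width gives a constant profile
  img2 <- matrix(0, 21, 60)
  img2[9:13, cols] <- 7
  pr5 <- extract_axial_profile(img2, mask, width_px = 5)
  expect_true(all(abs(pr5$intensity - 7) < 1e-9))
  # profile length equals the medial-axis path length (1-px steps)
  expect_equal(nrow(pr5), nrow(polegrow:::medial_axis_path(mask)))

  expect_error(extract_axial_profile(img, mask, width_px = 4),
               class = "polegrow_config_error")
  expect_error(extract_axial_profile(img, mask * 0),
               class = "polegrow_precondition_error")
})

test_that("full synthetic pipeline orients >= 99% of noisy non-founder tracks correctly", {
  cfg <- sim_config(n_founders = 6, n_generations = 3, seed = 33,
                    localization_mode = "old_pole", noise_sd = 10) # 10% of amplitude
  lin <- simulate_lineage(cfg)
  lab <- render_cohort_tracks(lin, cfg, "lab")
  oriented <- orient_track_new_to_old(lab, lin)
  non_f <- lin[!lin$founder, ]
  # after orientation, the old-pole spot must sit at the high-index end
  correct <- vapply(non_f$cell_id, function(id) {
    p <- oriented[oriented$cell_id == id & oriented$frame ==
                    min(oriented$frame[oriented$cell_id == id]), ]
    which.max(p$intensity) > nrow(p) / 2
  }, logical(1))
  expect_gte(mean(correct), 0.99)
})
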