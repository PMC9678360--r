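test_that("constant-rate growth and length-threshold division give exact interdivision times and pole shares", {
  lin <- simulate_lineage(tiny_config())
  founder <- lin[lin$founder, ][1, ]
  # +0.3 um/frame from 2 um: first frame at >= 4 um is frame 7
  expect_identical(founder$division_frame - founder$birth_frame, 7L)
  expect_equal(founder$truth_growth_old_um, 0.2 * 7)
  expect_equal(founder$truth_growth_new_um, 0.1 * 7)
  # closed form: old-pole share = rate_old / total for every cell
  shares <- lin$truth_growth_old_um /
    (lin$truth_growth_old_um + lin$truth_growth_new_um)
  expect_equal(shares, rep(2 / 3, nrow(lin)))
})

test_that("per-pole ground truth conserves total elongation exactly", {
  for (seed in 1:5) {
    cfg <- sim_config(rate_old = runif(1, 0, 0.3), rate_new = runif(1, 0, 0.3),
                      n_founders = 3, n_generations = 3, seed = seed)
    if (cfg$rate_old + cfg$rate_new == 0) next
    lin <- simulate_lineage(cfg)
    expect_equal(lin$truth_growth_old_um + lin$truth_growth_new_um,
                 lin$division_length_um - lin$birth_length_um)
    expect_true(all(vapply(lin$length_series, function(s) all(diff(s) >= 0),
                           logical(1))))
    expect_true(all(lin$truth_septum_rel > 0.2 & lin$truth_septum_rel < 0.8,
                    na.rm = TRUE))
  }
})

test_that("symmetric rates give identical per-pole growth; zero rates give non-dividing founders", {
  sym <- simulate_lineage(tiny_config(rate_old = 0.1, rate_new = 0.1))
  expect_equal(sym$truth_growth_old_um, sym$truth_growth_new_um)

  frozen <- simulate_lineage(sim_config(rate_old = 0, rate_new = 0,
                                        n_founders = 3, n_generations = 1,
                                        seed = 9))
  expect_identical(nrow(frozen), 3L)
  expect_true(all(frozen$founder))
  expect_true(all(is.na(frozen$division_frame)))
  expect_true(all(vapply(frozen$length_series, function(s)
    all(s == s[1]), logical(1))))
})

test_that("increasing the old-pole rate never decreases any cell's old-pole growth", {
  base <- simulate_lineage(tiny_config(rate_old = 0.1))
  for (r in c(0.15, 0.2, 0.3)) {
    lin <- simulate_lineage(tiny_config(rate_old = r))
    expect_true(all(lin$truth_growth_old_um[seq_len(nrow(base))] >=
                      base$truth_growth_old_um - 1e-12))
  }
})

test_that("pole ages and lineage bookkeeping follow the inheritance rule", {
  cfg <- sim_config(n_founders = 1, n_generations = 3, seed = 5)
  lin <- simulate_lineage(cfg)
  expect_true(all(lin$old_pole_age[lin$founder] == 1L))
  non_f <- lin[!lin$founder, ]
  # every non-founder inherits one pre-existing pole: age >= 2
  expect_true(all(non_f$old_pole_age >= 2L))
  # daughters are born at the mother's division frame
  mothers <- lin[match(non_f$mother_id, lin$cell_id), ]
  expect_identical(non_f$birth_frame, mothers$division_frame)
  # the two daughters partition the mother's division length
  lens <- tapply(non_f$birth_length_um, non_f$mother_id, sum)
  expect_equal(as.numeric(lens[mothers$cell_id[!duplicated(mothers$cell_id)]]),
               mothers$division_length_um[!duplicated(mothers$cell_id)])
})

test_that("the seed fully determines the lineage", {
  cfg <- sim_config(noise_sd = 2, seed = 11)
  a <- simulate_lineage(cfg)
  b <- simulate_lineage(cfg)
  expect_identical(a, b)
  c <- simulate_lineage(sim_config(noise_sd = 2, seed = 12))
  expect_false(identical(a$truth_septum_rel, c$truth_septum_rel))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(division_length = 2, birth_length = 3),
               class = "polegrow_config_error")
  expect_error(sim_config(localization_mode = "nonsense"),
               class = "polegrow_config_error")
  expect_error(sim_config(rate_old = 0, rate_new = 0, n_generations = 2),
               class = "polegrow_config_error")
  expect_error(sim_config(septum_rel_position_mean = 1.2),
               class = "polegrow_config_error")
})

test_that("JSON configs round-trip and unknown keys are rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(rate_old = 0.2, rate_new = 0.1, seed = 3),
                       path, auto_unbox = TRUE)
  cfg <- read_sim_config(path)
  expect_equal(cfg$rate_old, 0.2)
  jsonlite::write_json(list(rate_old = 0.2, bogus_key = 1), path,
                       auto_unbox = TRUE)
  expect_error(read_sim_config(path), class = "polegrow_config_error")
})
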