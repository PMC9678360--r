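worked_table <- function() {
  tibble::tibble(strain = rep(c("A", "B"), each = 3),
                 replicate = rep(1:3, 2),
                 median_value = c(1, 2, 3, 2, 4, 3))
}

test_that("replicate medians use the standard even/odd rules and require balance", {
  meas <- tibble::tibble(
    strain = rep(c("A", "B"), c(3, 4)),
    replicate = rep(1, 7),
    share_old = c(1, 3, 2, 1, 2, 3, 4)
  )
  meas2 <- dplyr::mutate(meas, replicate = 2)
  med <- replicate_medians(dplyr::bind_rows(meas, meas2))
  expect_equal(med$median_value[med$strain == "A"], c(2, 2))
  expect_equal(med$median_value[med$strain == "B"], c(2.5, 2.5))
  # missing (strain, replicate) cell: balance error listing the pair
  unbalanced <- dplyr::bind_rows(meas, meas2[meas2$strain == "A", ])
  expect_error(replicate_medians(unbalanced), class = "polegrow_balance_error")
})

test_that("the repeated-measures ANOVA matches the hand-computed sums of squares", {
  fit <- paired_oneway_anova(worked_table())
  expect_equal(fit$ss_strain, 1.5)
  expect_equal(fit$ss_block, 3)
  expect_equal(fit$ss_error, 1)
  expect_equal(fit$F_statistic, 3)
  expect_equal(c(fit$df_between, fit$df_error), c(1, 2))
  expect_equal(fit$p_value, pf(3, 1, 2, lower.tail = FALSE))
})

test_that("the ANOVA agrees with aov's within-block decomposition", {
  withr::local_seed(2)
  tb <- tidyr::expand_grid(strain = c("A", "B", "C"), replicate = 1:4) |>
    dplyr::mutate(median_value = rnorm(12) + (strain == "C"))
  fit <- paired_oneway_anova(tb)
  a <- summary(stats::aov(median_value ~ strain + Error(factor(replicate)),
                          data = tb))
  tab <- a[["Error: Within"]][[1]]
  expect_equal(fit$F_statistic, tab["strain", "F value"], tolerance = 1e-10)
  expect_equal(fit$p_value, tab["strain", "Pr(>F)"], tolerance = 1e-10)
})

test_that("for two strains F equals the squared paired t statistic", {
  withr::local_seed(3)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    tb <- tibble::tibble(strain = rep(c("A", "B"), each = n),
                         replicate = rep(seq_len(n), 2),
                         median_value = rnorm(2 * n))
    fit <- paired_oneway_anova(tb)
    d <- tb$median_value[tb$strain == "A"] - tb$median_value[tb$strain == "B"]
    t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
    expect_equal(fit$F_statistic, t_stat^2, tolerance = 1e-9)
    expect_equal(fit$p_value,
                 2 * pt(abs(t_stat), n - 1, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("F is invariant to shifting and positive scaling", {
  tb <- worked_table()
  f0 <- paired_oneway_anova(tb)$F_statistic
  shifted <- dplyr::mutate(tb, median_value = median_value + 17)
  scaled <- dplyr::mutate(tb, median_value = median_value * 3.5)
  expect_equal(paired_oneway_anova(shifted)$F_statistic, f0)
  expect_equal(paired_oneway_anova(scaled)$F_statistic, f0)
})

test_that("the F-test p-value agrees with an exact within-block permutation null", {
  # continuous data, enough blocks that the sign-flip null is fine-grained
  withr::local_seed(4)
  n <- 8
  tb <- tibble::tibble(strain = rep(c("A", "B"), each = n),
                       replicate = rep(seq_len(n), 2),
                       median_value = c(rnorm(n), rnorm(n, 0.6)))
  fit <- paired_oneway_anova(tb)
  d <- tb$median_value[tb$strain == "A"] - tb$median_value[tb$strain == "B"]
  f_perm <- function(dd) {
    m <- mean(dd)
    (m / (stats::sd(dd) / sqrt(length(dd))))^2
  }
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  f_null <- apply(signs, 1, function(s) f_perm(d * s))
  p_exact <- mean(f_null >= fit$F_statistic - 1e-12)
  expect_lt(abs(p_exact - fit$p_value), 0.05)
})

test_that("identical tables, degenerate fits and bad designs are handled", {
  flat <- dplyr::mutate(worked_table(), median_value = 5)
  fit_flat <- paired_oneway_anova(flat)
  expect_equal(fit_flat$ss_strain, 0)
  expect_equal(fit_flat$F_statistic, 0)
  # strain effect with zero residual: degenerate, flagged
  degen <- dplyr::mutate(worked_table(),
                         median_value = rep(c(1, 2), each = 3))
  fit_d <- paired_oneway_anova(degen)
  expect_true(fit_d$degenerate)
  expect_equal(fit_d$F_statistic, Inf)
  expect_equal(fit_d$p_value, 0)
  expect_error(paired_oneway_anova(worked_table()[1:4, ]),
               class = "polegrow_balance_error")
  expect_error(paired_oneway_anova(worked_table()[c(1, 4), ]),
               class = "polegrow_precondition_error")
})

test_that("pairwise contrasts against a reference strain are Holm-adjusted", {
  withr::local_seed(5)
  tb <- tidyr::expand_grid(strain = c("ref", "s1", "s2"), replicate = 1:4) |>
    dplyr::mutate(median_value = rnorm(12) + 2 * (strain == "s2"))
  fit <- paired_oneway_anova(tb, reference = "ref")
  expect_equal(nrow(fit$contrasts), 2)
  raw <- fit$contrasts$p_value
  expect_equal(fit$contrasts$p_adjusted,
               stats::p.adjust(raw, method = "holm"))
  td <- tidy(fit)
  expect_true(any(grepl("contrast", td$term)))
  gl <- glance(fit)
  expect_equal(gl$statistic, fit$F_statistic)
})
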