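test_that("weight-based comparator formula", {
  expect_equal(weight_based_dose(70), 112)
  expect_equal(weight_based_dose(70, snap = TRUE), 112.5)
  expect_equal(weight_based_dose(100), 160)
  expect_error(weight_based_dose(0), "positive")
})

test_that("joint T4+TSH objective normalizes the two scales", {
  expect_equal(t4tsh_objective(75, 2.5, 75, 2.5), 0)
  expect_equal(t4tsh_objective(75 + 60, 2.5, 75, 2.5), 1)
  expect_equal(t4tsh_objective(75 + 30, 2.5 + 2, 75, 2.5), 1)
  expect_true(all(t4tsh_objective(c(10, 200), c(0.1, 90), 75, 2.5) >= 0))
})

test_that("argmin tie-breaks select the lower dose deterministically", {
  expect_equal(hptsim:::pick_best(c(100, 112.5), c(0.3, 0.3)), 100)
  expect_equal(hptsim:::pick_best(c(100, 112.5, 125), c(Inf, 0.2, 0.2)), 112.5)
  expect_error(hptsim:::pick_best(c(100), Inf), "failed")
})

test_that("TSH-targeted grid search equals an independent exhaustive sweep", {
  grid <- c(87.5, 112.5, 137.5)
  fit <- optimize_lt4_tsh(ref_female, grid = grid, days = 42,
                          params = ref_params)
  # independent oracle: simulate each dose directly and take the argmin
  pd <- apply_rtf(ref_female_pp(), 0)
  finals <- vapply(grid, function(d) {
    tr <- run_course(pd, dose_regimen(lt4 = d), days = 42,
                     init = ref_female_ic(), sample_by = 42 * 24)
    tr$tsh_mUL[nrow(tr)]
  }, numeric(1))
  expect_equal(fit$dose, grid[which.min(abs(finals - 1.8))])
  expect_equal(fit$sweep$tsh_mUL, finals, tolerance = 1e-8)
  # two-dose grid straddling the target picks the closer dose
  two <- optimize_lt4_tsh(ref_female, grid = c(100, 125), days = 42,
                          params = ref_params)
  f2 <- two$sweep$tsh_mUL
  expect_true(f2[1] > 1.8 && f2[2] < 1.8)  # straddles
  expect_equal(two$dose, c(100, 125)[which.min(abs(f2 - 1.8))])
  # singleton grid returns its only candidate
  one <- optimize_lt4_tsh(ref_female, grid = 100, days = 42,
                          params = ref_params)
  expect_equal(one$dose, 100)
})

test_that("joint-target search reduces to TSH-only when TSH dominates", {
  grid <- c(87.5, 112.5, 137.5)
  fit <- optimize_lt4_t4tsh(ref_female, grid = grid, days = 42,
                            params = ref_params, b = 1.8)
  expect_equal(fit$dose, hptsim:::pick_best(
    grid, t4tsh_objective(fit$sweep$t4_ugL, fit$sweep$tsh_mUL, 75, 1.8)))
  # in the limit of infinite TSH weight only the TSH term matters
  tsh_only <- grid[which.min(abs(fit$sweep$tsh_mUL - 1.8))]
  ref_fit <- optimize_lt4_tsh(ref_female, grid = grid, days = 42,
                              params = ref_params)
  expect_equal(tsh_only, ref_fit$dose)
  one <- optimize_lt4_t4tsh(ref_female, grid = 112.5, days = 42,
                            params = ref_params)
  expect_equal(one$dose, 112.5)
})

test_that("optimized dose grows with body size and falls with RTF", {
  doses <- vapply(c(52, 70, 90), function(w)
    optimize_lt4_tsh(patient_profile("female", 1.63, w),
                     days = 42, params = ref_params)$dose, numeric(1))
  expect_true(all(diff(doses) >= 0))
  expect_gt(doses[3], doses[1])
  grid <- seq(75, 225, by = 25)
  d_rtf0 <- optimize_lt4_tsh(ref_female, rtf = 0, grid = grid, days = 42,
                             params = ref_params)$dose
  d_rtf3 <- optimize_lt4_tsh(ref_female, rtf = 0.3, grid = grid, days = 42,
                             params = ref_params)$dose
  expect_lte(d_rtf3, d_rtf0)
})

test_that("combination search equals an exhaustive 2-D sweep", {
  g4 <- c(75, 100); g3 <- c(0, 5)
  fit <- optimize_combo(ref_female, rtf = 0.10, schedule = "daily",
                        grid_lt4 = g4, grid_lt3 = g3, days = 50,
                        params = ref_params)
  # independent oracle: enumerate all pairs with direct steady-state runs
  pd <- apply_rtf(ref_female_pp(), 0.10)
  mids <- range_midpoints(normal_ranges())
  halfw <- c(t4 = 30, t3 = 0.6, tsh = 2)
  best <- NULL
  for (l3 in g3) for (l4 in g4) {
    ss <- steady_state(pd, dose_regimen(lt4 = l4, lt3 = l3), days = 50,
                       init = ref_female_ic(), warn = FALSE)
    if (!ss$converged) next
    sc <- sum(abs(ss$day_mean[c("t4_ugL", "t3_ugL", "tsh_mUL")] - mids) / halfw)
    if (is.null(best) || sc < best$sc) best <- list(l4 = l4, l3 = l3, sc = sc)
  }
  expect_equal(c(fit$lt4, fit$lt3), c(best$l4, best$l3))
  expect_equal(fit$score, best$sc, tolerance = 1e-10)
})

test_that("a euthyroid patient needs no supplementation", {
  fit <- optimize_combo(ref_female, rtf = 1, schedule = "daily",
                        grid_lt4 = c(0, 75), grid_lt3 = c(0, 5),
                        days = 50, params = ref_params)
  expect_equal(c(fit$lt4, fit$lt3), c(0, 0))
})

test_that("dose accuracy counts tablet-increment agreement", {
  expect_true(dose_accuracy(100, 112.5))    # boundary inclusive
  expect_false(dose_accuracy(100, 125))
  expect_equal(dose_accuracy(c(100, 100, 50, 75), c(112.5, 125, 50, 100)),
               c(TRUE, FALSE, TRUE, FALSE))
  expect_error(dose_accuracy(-5, 100), "non-negative")
  cohort <- data.frame(predicted = c(100, 100, 150, 200),
                       empirical = c(112.5, 125, 150, 250),
                       bmi = c(22, 24, 28, 35))
  acc <- cohort_accuracy(cohort)
  expect_equal(acc$overall, 0.5)
  expect_equal(unname(acc$by_bin), c(0.5, 1, 0))
  # empty bin reported as missing
  acc2 <- cohort_accuracy(cohort[1:2, ])
  expect_true(is.na(acc2$by_bin[["BMI>=32"]]))
})
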