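test_that("euthyroid trajectory is stationary with a daily TSH rhythm", {
  p <- ref_params
  tr <- cached("eu50", run_course(p, dose_regimen(), days = 50,
                                  init = ref_ic()))
  day <- function(d) tr[tr$time_h >= (d - 1) * 24 & tr$time_h < d * 24, ]
  m1 <- colMeans(day(1)[, c("t4_ugL", "t3_ugL", "tsh_mUL")])
  m49 <- colMeans(day(49)[, c("t4_ugL", "t3_ugL", "tsh_mUL")])
  m50 <- colMeans(day(50)[, c("t4_ugL", "t3_ugL", "tsh_mUL")])
  # the cycle-averaged root sits within 2% of the circadian limit cycle
  # (the slow tissue pool relaxes onto the cycle over weeks), and by day 50
  # consecutive day-averages agree to the 0.5% stationarity criterion
  expect_true(all(abs(m50 - m1) / m1 < 0.02))
  expect_true(all(abs(m50 - m49) / m49 < 5e-3))
  # TSH oscillates daily within the normal range
  last <- day(50)
  expect_gt(min(last$tsh_mUL), 0.5)
  expect_lt(max(last$tsh_mUL), 4.5)
  expect_gt(max(last$tsh_mUL) - min(last$tsh_mUL), 0.3)
  # ~24-h periodicity of the rhythm
  prev <- day(49)
  expect_equal(last$tsh_mUL[1:24], prev$tsh_mUL[1:24], tolerance = 1e-3)
  # T4 stays near its euthyroid level throughout
  eu <- to_concentrations(ref_ic(), p)
  expect_lt(max(abs(tr$t4_ugL - eu[["t4_ugL"]])) / eu[["t4_ugL"]], 0.05)
})

test_that("simulated thyroidectomy sends TSH to its plateau and T4 low", {
  pp <- ref_female_pp()
  tr <- cached("tx50", run_course(apply_rtf(pp, 0), dose_regimen(),
                                  days = 50, init = ref_female_ic()))
  expect_gt(tr$tsh_mUL[nrow(tr)], 800)
  expect_lt(tr$t4_ugL[nrow(tr)], 45)       # below the normal minimum
  expect_true(all(diff(tr$tsh_mUL[tr$time_h %% 24 == 0]) > -1))  # rising to plateau
  # TSH fluctuations cease in extreme hypothyroidism
  last <- tr[tr$time_h >= 49 * 24, "tsh_mUL"]
  expect_lt((max(last) - min(last)) / mean(last), 0.01)
})

test_that("dose-time hormone values are stable under sampling refinement", {
  pp <- apply_rtf(ref_female_pp(), 0)
  reg <- dose_regimen(lt4 = 112.5)
  t1 <- run_course(pp, reg, days = 5, init = ref_female_ic(), sample_by = 1)
  t2 <- run_course(pp, reg, days = 5, init = ref_female_ic(), sample_by = 0.25)
  at <- intersect(t1$time_h, t2$time_h)
  i1 <- match(at, t1$time_h); i2 <- match(at, t2$time_h)
  expect_equal(t1$t4_ugL[i1], t2$t4_ugL[i2], tolerance = 1e-4)
  expect_equal(t1$tsh_mUL[i1], t2$tsh_mUL[i2], tolerance = 1e-4)
})

test_that("steady state converges by 50 days and is stable to 100", {
  p <- ref_params
  s50 <- cached("ss50", steady_state(p, days = 50, init = ref_ic()))
  expect_true(s50$converged)
  s100 <- steady_state(p, days = 100, init = ref_ic())
  expect_true(all(abs(s100$day_mean - s50$day_mean) / s50$day_mean < 0.005))
  # matches the algebraic root of the cycle-averaged RHS
  root <- to_concentrations(ref_ic(), p)
  expect_true(all(abs(s50$day_mean - root) / root < 0.01))
})

test_that("concentration conversion is a volume-scaled bijection", {
  p <- ref_params
  expect_equal(unname(to_concentrations(rep(0, 19), p)), c(0, 0, 0))
  st <- ref_ic()
  c1 <- to_concentrations(st, p)
  p2 <- p; p2[["Vp"]] <- 2 * p[["Vp"]]
  c2 <- to_concentrations(st, p2)
  expect_equal(c2[["t4_ugL"]], c1[["t4_ugL"]] / 2)
  expect_equal(c2[["t3_ugL"]], c1[["t3_ugL"]] / 2)
  back <- hptsim:::from_concentrations(c1, p)
  expect_equal(back[["T4_plasma"]], st[["T4_plasma"]])
  expect_equal(back[["TSH_plasma"]], st[["TSH_plasma"]])
  # matrix form agrees with vector form
  m <- to_concentrations(rbind(st, st), p)
  expect_equal(unname(m[1, ]), unname(c1))
})

test_that("split and continuous dosing reduce T3 fluctuations in order", {
  pp <- apply_rtf(ref_female_pp(), 0.15)
  ic <- ref_female_ic()
  fluct <- function(reg) {
    tr <- run_course(pp, reg, days = 50, init = ic)
    x <- tr$t3_ugL[tr$time_h >= 49 * 24]
    max(x) - min(x)
  }
  f_daily <- fluct(dose_regimen(lt4 = 100, lt3 = 10))
  f_split <- fluct(dose_regimen(lt4 = 50, lt3 = 5, interval = 12))
  f_inf <- fluct(dose_regimen(lt4 = 100, t3_infusion = 10 / 24))
  expect_lt(f_split, f_daily)
  expect_lt(f_inf, f_split)
})

test_that("dose regimens validate their fields", {
  expect_error(dose_regimen(lt4 = -1), "lt4")
  expect_error(dose_regimen(interval = 0), "interval")
  expect_error(dose_regimen(t3_infusion = -2), "t3_infusion")
  r <- dose_regimen(lt4 = 100, duration = 42)
  expect_equal(r$duration, 42)
})
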