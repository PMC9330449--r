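test_that("ideal body weight follows the sex-specific quadratics", {
  # frozen against direct evaluation of the quadratics
  expect_equal(ideal_body_weight(1.76, "male"), 77.6696, tolerance = 1e-6)
  expect_equal(ideal_body_weight(1.67, "female"), 62.547995, tolerance = 1e-6)
  expect_equal(ideal_body_weight(1.70, "male"), 71.495, tolerance = 1e-6)
  # positive over the supported height range
  for (h in seq(1.2, 2.2, by = 0.1)) {
    expect_gt(ideal_body_weight(h, "m"), 0)
    expect_gt(ideal_body_weight(h, "f"), 0)
  }
  expect_error(ideal_body_weight(-1, "male"), "positive")
  expect_warning(ideal_body_weight(1.1, "male"), "1.2-2.2")
})

test_that("percent deviation from ideal weight", {
  ibw <- ideal_body_weight(1.67, "female")
  expect_equal(pct_deviation_ibw(ibw, 1.67, "female"), 0)
  expect_equal(pct_deviation_ibw(63, 1.67, "female"), 0.7226531,
               tolerance = 1e-6)
  expect_equal(pct_deviation_ibw(67.53, 1.76, "male"), -13.05484,
               tolerance = 1e-5)
  expect_error(pct_deviation_ibw(0, 1.67, "female"), "positive")
})

test_that("blood volume per kg decreases with excess weight", {
  expect_equal(blood_volume(63, 1.67, "female"), 4.437962, tolerance = 1e-6)
  # per-kg value strictly decreasing in weight at fixed height
  w <- seq(45, 110, by = 5)
  perkg <- vapply(w, function(x) blood_volume(x, 1.67, "female") / x,
                  numeric(1))
  expect_true(all(diff(perkg) < 0))
  # total volume still increases with weight, and with height at fixed weight
  tot <- vapply(w, function(x) blood_volume(x, 1.67, "female"), numeric(1))
  expect_true(all(diff(tot) > 0))
  h <- seq(1.4, 2.0, by = 0.1)
  byh <- vapply(h, function(x) blood_volume(70, x, "male"), numeric(1))
  expect_true(all(diff(byh) > 0))
})

test_that("plasma volume from blood volume and hematocrit", {
  expect_equal(plasma_volume_raw(63, 1.67, "female", 0.40), 2.662777,
               tolerance = 1e-6)
  expect_equal(plasma_volume_raw(67.52768, 1.76, "male", 0.45), 2.869132,
               tolerance = 1e-6)
  # hematocrit -> 1 gives vanishing plasma volume
  expect_lt(plasma_volume_raw(63, 1.67, "female", 0.999), 0.01)
  expect_error(plasma_volume_raw(63, 1.67, "female", 1.2), "between 0 and 1")
  expect_error(plasma_volume_raw(63, 1.67, "female", 0), "between 0 and 1")
  # defaults are sex specific
  expect_equal(plasma_volume_raw(63, 1.67, "female"),
               plasma_volume_raw(63, 1.67, "female", 0.40))
  expect_equal(plasma_volume_raw(63, 1.67, "male"),
               plasma_volume_raw(63, 1.67, "male", 0.45))
})

test_that("reference plasma volume and volume rescaling", {
  expect_equal(reference_plasma_volume(ref_params), 2.774927, tolerance = 1e-6)
  pf <- patient_profile("female", 1.67, 23 * 1.67^2)
  expect_equal(plasma_volume_scaled(pf, ref_params), 3.091364,
               tolerance = 1e-6)
  # construction: mean scaled volume over the two reference patients is 3.2
  pm <- patient_profile("male", 1.76, 21.8 * 1.76^2)
  expect_equal((plasma_volume_scaled(pf, ref_params) +
                  plasma_volume_scaled(pm, ref_params)) / 2, 3.2)
  # reference volume moves monotonically with the female reference BMI
  vref <- vapply(c(21, 23, 25, 27), function(b)
    reference_plasma_volume(hpt_params(BMI_Fref = b)), numeric(1))
  expect_true(all(diff(vref) > 0))
})

test_that("TSH distribution volume preserves the 2 L tissue space", {
  expect_equal(tsh_distribution_volume(3.2), 5.2)
  expect_equal(tsh_distribution_volume(3.09), 5.09)
  expect_equal(tsh_distribution_volume(4.0), 6.0)
  expect_gt(tsh_distribution_volume(0.1), 2.0)
  expect_error(tsh_distribution_volume(-1), "positive")
})

test_that("allometric T3 clearance scaling", {
  bw_f <- 23 * 1.67^2
  bw_m <- 21.8 * 1.76^2
  expect_equal(t3_clearance_scaled(patient_profile("female", 1.67, bw_f),
                                   ref_params), 0.185)
  expect_equal(t3_clearance_scaled(patient_profile("male", 1.76, bw_m),
                                   ref_params), 1.05 * 0.185)
  expect_equal(t3_clearance_scaled(patient_profile("female", 1.67, 2 * bw_f),
                                   ref_params), 0.3111317, tolerance = 1e-6)
  # homogeneity: doubling the patient and the reference weight cancels
  p2 <- hpt_params(BMI_Fref = 2 * 23)
  expect_equal(t3_clearance_scaled(patient_profile("female", 1.67, 2 * bw_f),
                                   p2), 0.185)
})

test_that("patient profiles derive BMI and default hematocrit", {
  p <- patient_profile("F", 1.67, 63)
  expect_equal(p$bmi, 63 / 1.67^2)
  expect_equal(p$hematocrit, 0.40)
  expect_equal(patient_profile("m", 1.76, 70)$hematocrit, 0.45)
  expect_equal(patient_profile("m", 1.76, 70, 0.5)$hematocrit, 0.5)
  expect_error(patient_profile("x", 1.7, 70), "male")
  expect_error(patient_profile("f", 1.7, -1), "positive")
  expect_error(patient_profile("f", 1.7, 70, 1.5), "between 0 and 1")
})

test_that("patient tables read with line-numbered validation errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,sex,height_m,weight_kg", "a,f,1.67,63", "b,M,1.80,85"), f)
  pts <- read_patients(f)
  expect_length(pts, 2)
  expect_equal(names(pts), c("a", "b"))
  expect_equal(pts[["b"]]$sex, "male")
  writeLines(c("id,sex,height_m,weight_kg", "a,f,1.67,63", "b,q,1.80,85"), f)
  expect_error(read_patients(f), "line 3")
  writeLines(c("id,sex,height_m", "a,f,1.67"), f)
  expect_error(read_patients(f), "weight_kg")
})
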