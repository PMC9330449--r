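test_that("negative log-likelihood matches closed forms and is additive", {
  # single observation at its mean with unit sigma
  expect_equal(neg_loglik(hormone_obs("T4", 1, 5), 5, c(T4 = 1)),
               log(2 * pi) / 2)
  # a one-sigma residual adds exactly 1/2
  expect_equal(neg_loglik(hormone_obs("T4", 1, 5), 7, c(T4 = 2)) -
                 neg_loglik(hormone_obs("T4", 1, 5), 5, c(T4 = 2)), 0.5)
  # additivity over channels
  o4 <- hormone_obs("T4", c(1, 2), c(80, 82))
  o3 <- hormone_obs("T3", c(1, 2), c(1.3, 1.5))
  both <- hormone_obs(c("T4", "T4", "T3", "T3"), c(1, 2, 1, 2),
                      c(80, 82, 1.3, 1.5))
  s <- c(T4 = 4, T3 = 0.2)
  expect_equal(neg_loglik(both, c(81, 81, 1.4, 1.4), s),
               neg_loglik(o4, c(81, 81), s) + neg_loglik(o3, c(1.4, 1.4), s))
  expect_error(neg_loglik(o4, c(81, 81), c(T4 = 0)), "positive")
  expect_error(neg_loglik(o4, 81, s), "align")
})

test_that("profiled sigma is the weighted RMS residual (stationarity)", {
  obs <- hormone_obs(rep("T4", 3), 1:3, c(80, 82, 84))
  pred <- c(81, 81, 81)
  s <- hptsim:::profile_sigmas(obs, pred)
  expect_equal(s[["T4"]], sqrt(mean((c(80, 82, 84) - 81)^2)))
  # weighting a point by 4 equals replicating it four times
  obs_w <- hormone_obs(rep("T4", 3), 1:3, c(80, 82, 84), weight = c(4, 1, 1))
  obs_r <- hormone_obs(rep("T4", 6), c(1, 1, 1, 1, 2, 3),
                       c(80, 80, 80, 80, 82, 84))
  expect_equal(hptsim:::profile_sigmas(obs_w, pred)[["T4"]],
               hptsim:::profile_sigmas(obs_r, c(81, 81, 81, 81, 81, 81))[["T4"]])
  # the profiled sigma is the stationary point of the likelihood
  f <- function(sg) neg_loglik(obs, pred, c(T4 = sg))
  expect_lt(f(s[["T4"]]), f(s[["T4"]] * 1.05))
  expect_lt(f(s[["T4"]]), f(s[["T4"]] * 0.95))
})

test_that("selected TSH observations can be emphasized", {
  obs <- hormone_obs(rep(c("T4", "TSH"), each = 30), rep(1:30, 2),
                     c(rep(80, 30), rep(2, 30)))
  s1 <- scale_tsh_points(obs, factor = 1)
  expect_identical(s1, obs)
  s100 <- scale_tsh_points(obs)
  expect_equal(sum(s100$weight != obs$weight), 4)
  expect_equal(s100$weight[30 + c(9, 13, 24, 28)], rep(100, 4))
  expect_identical(s100$value, obs$value)
  # composition: two factor-10 passes equal one factor-100 pass
  s10x2 <- scale_tsh_points(scale_tsh_points(obs, factor = 10), factor = 10)
  expect_equal(s10x2$weight, s100$weight)
  # value mode touches values instead
  sv <- scale_tsh_points(obs, indices = c(1, 2), factor = 100, mode = "value")
  expect_equal(sv$value[31:32], c(200, 200))
  expect_identical(sv$weight, obs$weight)
  expect_error(scale_tsh_points(obs, indices = 99), "out of range")
})

test_that("noise-free synthetic data recovers the generating parameters", {
  p <- ref_params
  designs <- lapply(c(400, 450, 600), euthyroid_challenge)
  obs <- lapply(designs, function(d)
    synth_timecourses(p, d, sigmas = c(T4 = 0, T3 = 0, TSH = 0), seed = 7))
  truth <- c(S4 = p[["S4"]], k05 = p[["k05"]])
  fit <- fit_parameters(obs, designs, free = c("S4", "k05"),
                        init = truth * c(1.1, 0.9), restarts = 1)
  expect_true(all(abs(fit$estimates - truth) / truth < 0.01))
  expect_true(all(unlist(fit$sigmas) < 1e-4))  # near-exact fit
  # fixing all parameters evaluates the likelihood without moving anything
  fit0 <- fit_parameters(obs[[1]], designs[[1]], free = character(0))
  expect_length(fit0$estimates, 0)
  expect_true(is.finite(fit0$nll))
  expect_error(fit_parameters(obs, designs, free = "k12"), "not estimable")
})

test_that("inverse-Hessian %CVs match a known quadratic curvature", {
  A <- matrix(c(4, 1, 1, 2), 2)
  th0 <- c(2, 5)
  f <- function(x) as.numeric(0.5 * t(x - th0) %*% A %*% (x - th0) + 3)
  cv <- parameter_cvs(f, c(a = 2, b = 5))
  expect_equal(unname(cv), 100 * sqrt(diag(solve(A))) / th0,
               tolerance = 1e-4)
  # a parameter with no curvature yields missing values with a warning
  g <- function(x) 2 * (x[1] - 1)^2
  expect_warning(cvg <- parameter_cvs(g, c(a = 1, dummy = 3)),
                 "singular|positive definite")
  expect_true(is.na(cvg[["dummy"]]))
})

test_that("B0 calibration hits a requested TSH plateau", {
  p300 <- calibrate_b0(300, ref_params)
  expect_equal(attr(p300, "plateau"), 300, tolerance = 1e-3)
  expect_lt(p300[["B0"]], ref_params[["B0"]])  # lower ceiling, lower mean rate
  # plateau scales ~ proportionally with B0
  expect_equal(p300[["B0"]] / ref_params[["B0"]], 300 / 913.9,
               tolerance = 0.05)
})
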