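#' Synthetic blood-volume scatter
#'
#' Emulates the structure of a per-kg blood-volume dataset: percent
#' deviations from ideal weight drawn uniformly on \[-40, +100\]%, with
#' per-kg blood volume (ml/kg) given by the two-parameter anthropometric
#' curve `1000 a (100 + delta)^(n_bv - 1)` plus Gaussian noise. With zero
#' noise the points lie exactly on the curve, so least-squares refitting
#' recovers `a = 1.27` and `n_bv = 0.373`. Deterministic given `seed`.
#'
#' @param n_per_sex Points per sex (>= 2).
#' @param noise_sd Gaussian noise SD in ml/kg (default 3, a realistic
#'   measurement scatter).
#' @param seed Integer seed.
#' @return Data frame with `sex`, `pct_dev_ibw`, `vb_ml_per_kg`.
#' @export
synth_blood_volume_data <- function(n_per_sex = 50, noise_sd = 3, seed = 1L) {
  stopifnot(n_per_sex >= 2, noise_sd >= 0)
  k <- bv_constants()
  with_seed(seed, {
    d <- stats::runif(2 * n_per_sex, -40, 100)
    vb <- 1000 * k[["a"]] * (100 + d)^(k[["n_bv"]] - 1) +
      stats::rnorm(2 * n_per_sex, 0, noise_sd)
    data.frame(sex = rep(c("male", "female"), each = n_per_sex),
               pct_dev_ibw = d, vb_ml_per_kg = vb)
  })
}

#' Refit the blood-volume curve
#'
#' Nonlinear least squares of `vb_ml_per_kg ~ 1000 a (100 + delta)^(n_bv-1)`
#' on a (synthetic or user) scatter table; the recovery counterpart of
#' [synth_blood_volume_data()].
#'
#' @param data Data frame with `pct_dev_ibw` and `vb_ml_per_kg`.
#' @param start Starting values for `a` and `n_bv`.
#' @return Named vector `c(a, n_bv)` of fitted constants.
#' @export
fit_blood_volume <- function(data, start = c(a = 1, n_bv = 0.5)) {
  # scaleOffset keeps the convergence test meaningful on zero-residual data
  fit <- stats::nls(vb_ml_per_kg ~ 1000 * a * (100 + pct_dev_ibw)^(n_bv - 1),
                    data = data, start = as.list(start),
                    control = stats::nls.control(maxiter = 200, scaleOffset = 1))
  stats::coef(fit)
}

#' Synthetic patient cohort with empirical doses
#'
#' Generates a cohort of anthropometric profiles (sex Bernoulli(1/2); height
#' normal by sex, means 1.76 / 1.63 m, SD 0.07; BMI log-normal with median
#' 26) and, optionally, an "empirical" euthyroid LT4 dose for each patient:
#' the model's own TSH-targeted optimized dose plus a tablet-increment
#' jitter drawn from `{-jitter, 0, +jitter}`. With `jitter = 0` the scoring
#' protocol is self-consistent (accuracy 1 in every BMI bin). The cohort
#' distributions are invented emulation, not estimates from any dataset.
#'
#' @param n Cohort size (>= 1).
#' @param seed Integer seed.
#' @param sex Optional fixed sex (`"male"`/`"female"`) instead of random.
#' @param empirical_dose Also compute the model-based empirical dose column
#'   (runs the dose optimizer per patient; substantially slower).
#' @param jitter Dose jitter magnitude, ug (default 12.5).
#' @param grid,days Passed to [optimize_lt4_tsh()] when doses are computed.
#' @param params Reference [hpt_params()].
#' @return Data frame with `id`, `sex`, `height_m`, `weight_kg`, `bmi` and,
#'   when requested, `empirical_dose` (ug/day).
#' @export
synth_cohort <- function(n, seed = 1L, sex = NULL, empirical_dose = FALSE,
                         jitter = 12.5, grid = lt4_grid(), days = 42,
                         params = hpt_params()) {
  stopifnot(n >= 1)
  df <- with_seed(seed, {
    sx <- if (is.null(sex)) ifelse(stats::runif(n) < 0.5, "male", "female")
          else rep(match_sex(sex), n)
    h <- stats::rnorm(n, ifelse(sx == "male", 1.76, 1.63), 0.07)
    h <- pmin(pmax(h, 1.4), 2.1)
    bmi <- stats::rlnorm(n, log(26), 0.15)
    jit <- sample(c(-1, 0, 1), n, replace = TRUE) * jitter
    data.frame(id = seq_len(n), sex = sx, height_m = h,
               weight_kg = bmi * h^2, bmi = bmi, jitter = jit)
  })
  if (empirical_dose) {
    pred <- vapply(seq_len(n), function(i) {
      pt <- patient_profile(df$sex[i], df$height_m[i], df$weight_kg[i])
      optimize_lt4_tsh(pt, grid = grid, days = days, params = params)$dose
    }, numeric(1))
    df$predicted_dose <- pred
    df$empirical_dose <- pmax(pred + df$jitter, min(grid))
  }
  df$jitter <- NULL
  df
}

#' Synthetic hormone time courses
#'
#' Simulates the model under a [fit_design()] protocol and adds independent
#' Gaussian noise with channel-specific standard deviations; negative draws
#' are truncated at zero (hormone concentrations are non-negative). With all
#' sigmas zero the observations equal the model predictions exactly.
#' Deterministic given `seed`.
#'
#' @param params An [hpt_params()] set.
#' @param design A [fit_design()].
#' @param times Sampling times (hours), shared across channels.
#' @param sigmas Named noise SDs `c(T4 = , T3 = , TSH = )` in concentration
#'   units.
#' @param seed Integer seed.
#' @return A [hormone_obs()] table.
#' @export
synth_timecourses <- function(params, design,
                              times = seq(0, design$duration_h, by = 4),
                              sigmas = c(T4 = 5, T3 = 0.1, TSH = 0.3),
                              seed = 1L) {
  stopifnot(all(c("T4", "T3", "TSH") %in% names(sigmas)), all(sigmas >= 0))
  skeleton <- hormone_obs(rep(c("T4", "T3", "TSH"), each = length(times)),
                          rep(times, 3), 0)
  mu <- simulate_design(params, design, skeleton)
  noise <- with_seed(seed,
    stats::rnorm(nrow(skeleton), 0, sigmas[skeleton$channel]))
  skeleton$value <- pmax(mu + noise, 0)
  skeleton
}
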