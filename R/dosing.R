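#' Normal hormone reference ranges
#'
#' Target intervals used by the dose optimizers. TSH 0.5--4.5 mU/L; total T4
#' defaults to 45--105 ug/L (upper bound per the model's reference range,
#' lower bound the standard 4.5 ug/dL assay limit); total T3 defaults to the
#' standard 0.8--2.0 ug/L (80--200 ng/dL) interval. All configurable.
#'
#' @param tsh,t4,t3 Length-2 numeric `c(lower, upper)` intervals.
#' @return Object of class `normal_ranges` with a `midpoints()` helper via
#'   [range_midpoints()].
#' @export
normal_ranges <- function(tsh = c(0.5, 4.5), t4 = c(45, 105), t3 = c(0.8, 2.0)) {
  chk <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 2L || x[1] >= x[2])
      stop("`", nm, "` must be c(lower, upper) with lower < upper", call. = FALSE)
    x
  }
  structure(list(tsh = chk(tsh, "tsh"), t4 = chk(t4, "t4"), t3 = chk(t3, "t3")),
            class = "normal_ranges")
}

#' @rdname normal_ranges
#' @param ranges A `normal_ranges` object.
#' @return `range_midpoints()`: named vector of interval midpoints.
#' @export
range_midpoints <- function(ranges) {
  vapply(ranges[c("t4", "t3", "tsh")], function(r) mean(r), numeric(1))
}

#' Candidate dose grids
#'
#' The LT4 monotherapy grid spans 62.5 to 325 ug in 12.5-ug steps (22
#' values, the commercially available tablet increments); the LT3 grid for
#' combination therapy spans 0 to 20 ug in 2.5-ug steps.
#'
#' @return Numeric vector of candidate daily doses (ug).
#' @export
lt4_grid <- function() seq(62.5, 325, by = 12.5)

#' @rdname lt4_grid
#' @export
lt3_grid <- function() seq(0, 20, by = 2.5)

#' Weight-based comparator dose
#'
#' The conventional 1.6 ug LT4 per kg body weight formula, optionally
#' snapped to the nearest 12.5-ug tablet increment.
#'
#' @param weight Body weight in kg (> 0).
#' @param snap Snap to the nearest 12.5-ug grid value?
#' @return Daily LT4 dose in ug.
#' @examples
#' weight_based_dose(70)             # 112
#' weight_based_dose(70, snap = TRUE) # 112.5
#' @export
weight_based_dose <- function(weight, snap = FALSE) {
  if (!is.numeric(weight) || any(weight <= 0))
    stop("`weight` must be positive (kg)", call. = FALSE)
  d <- 1.6 * weight
  if (snap) d <- round(d / 12.5) * 12.5
  d
}

# deterministic argmin with tie-break to the first (lowest-dose) candidate
pick_best <- function(doses, scores) {
  ok <- is.finite(scores)
  if (!any(ok)) stop("all candidate simulations failed", call. = FALSE)
  doses[ok][which.min(scores[ok])]
}

# shared sweep of once-daily LT4 doses for a thyroidectomized (or rtf>0)
# patient; returns end-of-course T4/TSH per dose
lt4_sweep <- function(patient, rtf, grid, days, params, interval = 24,
                      rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(patient, "hpt_patient"))
  pp <- personalize(params, patient)
  init <- initial_condition(pp)
  pd <- apply_rtf(pp, rtf)
  res <- t(vapply(grid, function(d) {
    tr <- run_course(pd, dose_regimen(lt4 = d, interval = interval),
                     days = days, init = init, sample_by = days * 24,
                     rtol = rtol, atol = atol)
    fin <- unlist(tr[nrow(tr), c("t4_ugL", "t3_ugL", "tsh_mUL")])
    fin
  }, numeric(3)))
  data.frame(dose = grid, t4_ugL = res[, 1], t3_ugL = res[, 2],
             tsh_mUL = res[, 3])
}

#' Optimize LT4 monotherapy against a TSH target
#'
#' Simulates each candidate once-daily LT4 dose for `days` (default 42) in a
#' patient with residual thyroid function `rtf` (default 0, complete
#' thyroidectomy), starting from the patient's euthyroid state, and returns
#' the dose whose end-of-course (trough) TSH is closest to `target_tsh`
#' (default 1.8 mU/L). Ties break deterministically to the lower dose.
#'
#' @param patient An [patient_profile()].
#' @param rtf Residual thyroid function in \[0, 1\] (default 0).
#' @param target_tsh Target TSH, mU/L.
#' @param grid Candidate daily doses, ug (default [lt4_grid()]).
#' @param days Simulated treatment length, days.
#' @param params Reference [hpt_params()].
#' @param rtol,atol Solver tolerances.
#' @return List of class `dose_search`: `dose` (ug/day), `sweep` (per-dose
#'   end-of-course values), `target`, `objective` per dose.
#' @export
optimize_lt4_tsh <- function(patient, rtf = 0, target_tsh = 1.8,
                             grid = lt4_grid(), days = 42,
                             params = hpt_params(),
                             rtol = 1e-6, atol = 1e-9) {
  sweep <- lt4_sweep(patient, rtf, grid, days, params, rtol = rtol, atol = atol)
  obj <- abs(sweep$tsh_mUL - target_tsh)
  structure(list(dose = pick_best(sweep$dose, obj), sweep = sweep,
                 objective = obj, target = c(tsh = target_tsh)),
            class = "dose_search")
}

#' Joint T4 + TSH dosing objective
#'
#' Normalized L1 distance of end-of-course T4 (ug/L) and TSH (mU/L) from
#' their targets: `|T4 - a| / 60 + |TSH - b| / 4`. The divisors normalize
#' the scale difference between the two variables.
#'
#' @param t4,tsh Predicted end-of-course values.
#' @param a,b Target T4 (ug/L) and TSH (mU/L).
#' @return Non-negative score, zero iff both targets are met.
#' @export
t4tsh_objective <- function(t4, tsh, a, b) {
  abs(t4 - a) / 60 + abs(tsh - b) / 4
}

#' Optimize LT4 monotherapy against joint T4 + TSH targets
#'
#' As [optimize_lt4_tsh()] but minimizing [t4tsh_objective()] on the
#' end-of-course values. Targets default to the normal-range midpoints.
#'
#' @inheritParams optimize_lt4_tsh
#' @param a Target T4, ug/L (default the [normal_ranges()] T4 midpoint).
#' @param b Target TSH, mU/L (default the TSH midpoint).
#' @param ranges [normal_ranges()] supplying default targets.
#' @return A `dose_search` list.
#' @export
optimize_lt4_t4tsh <- function(patient, rtf = 0, a = NULL, b = NULL,
                               grid = lt4_grid(), days = 42,
                               params = hpt_params(), ranges = normal_ranges(),
                               rtol = 1e-6, atol = 1e-9) {
  mids <- range_midpoints(ranges)
  if (is.null(a)) a <- mids[["t4"]]
  if (is.null(b)) b <- mids[["tsh"]]
  sweep <- lt4_sweep(patient, rtf, grid, days, params, rtol = rtol, atol = atol)
  obj <- t4tsh_objective(sweep$t4_ugL, sweep$tsh_mUL, a, b)
  structure(list(dose = pick_best(sweep$dose, obj), sweep = sweep,
                 objective = obj, target = c(t4 = a, tsh = b)),
            class = "dose_search")
}

#' @export
print.dose_search <- function(x, ...) {
  cat("<dose_search> optimal dose:",
      if (!is.null(x$lt4)) paste0("LT4 ", x$lt4, " + LT3 ", x$lt3, " ug/day")
      else paste0(x$dose, " ug/day"), "\n")
  invisible(x)
}

#' Optimize LT4 + LT3 combination therapy
#'
#' Two-dimensional deterministic grid search over daily LT4 and LT3 amounts
#' for a patient with residual thyroid function, minimizing the normalized
#' L1 distance of the 50-day steady-state final-day mean T4/T3/TSH from the
#' normal-range midpoints: `sum_h |h - mid_h| / (width_h / 2)`. Schedules:
#' `"daily"` gives both drugs once daily; `"twice_daily"` splits each daily
#' amount into two half-doses 12 h apart; `"infusion"` gives LT4 once daily
#' plus the LT3 daily amount as a constant infusion (`lt3 / 24` ug/h).
#' Scenario conventions pair `daily` with RTF 10%, `twice_daily` with 15%
#' and `infusion` with 25%. Non-convergent grid points are flagged and
#' excluded from the argmin; ties break to the lowest LT3 then LT4 dose.
#'
#' @inheritParams optimize_lt4_tsh
#' @param rtf Residual thyroid function fraction.
#' @param schedule `"daily"`, `"twice_daily"` or `"infusion"`.
#' @param grid_lt4,grid_lt3 Candidate daily amounts, ug.
#' @param ranges Target [normal_ranges()].
#' @param days Days to steady state (default 50).
#' @return List of class `dose_search`: `lt4`, `lt3` (ug/day), `sweep` data
#'   frame with per-pair steady-state day means, `score` and `converged`.
#' @export
optimize_combo <- function(patient, rtf,
                           schedule = c("daily", "twice_daily", "infusion"),
                           grid_lt4 = seq(62.5, 325, by = 12.5),
                           grid_lt3 = lt3_grid(),
                           ranges = normal_ranges(), days = 50,
                           params = hpt_params(),
                           rtol = 1e-6, atol = 1e-9) {
  schedule <- match.arg(schedule)
  stopifnot(inherits(patient, "hpt_patient"))
  pp <- personalize(params, patient)
  init <- initial_condition(pp)
  pd <- apply_rtf(pp, rtf)
  mids <- range_midpoints(ranges)
  halfw <- vapply(ranges[c("t4", "t3", "tsh")], function(r) diff(r) / 2,
                  numeric(1))
  cases <- expand.grid(lt3 = grid_lt3, lt4 = grid_lt4)[, c("lt4", "lt3")]
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    l4 <- cases$lt4[i]; l3 <- cases$lt3[i]
    reg <- switch(schedule,
      daily = dose_regimen(lt4 = l4, lt3 = l3, interval = 24),
      twice_daily = dose_regimen(lt4 = l4 / 2, lt3 = l3 / 2, interval = 12),
      infusion = dose_regimen(lt4 = l4, lt3 = 0, interval = 24,
                              t3_infusion = l3 / 24))
    ss <- tryCatch(
      steady_state(pd, reg, days = days, init = init, rtol = rtol,
                   atol = atol, warn = FALSE),
      error = function(e) NULL)
    if (is.null(ss))
      return(data.frame(lt4 = l4, lt3 = l3, t4_ugL = NA_real_,
                        t3_ugL = NA_real_, tsh_mUL = NA_real_,
                        score = Inf, converged = FALSE))
    m <- ss$day_mean[c("t4_ugL", "t3_ugL", "tsh_mUL")]
    sc <- sum(abs(m - mids) / halfw)
    data.frame(lt4 = l4, lt3 = l3, t4_ugL = m[[1]], t3_ugL = m[[2]],
               tsh_mUL = m[[3]], score = sc, converged = ss$converged)
  })
  sweep <- do.call(rbind, rows)
  eligible <- sweep$converged & is.finite(sweep$score)
  if (!any(eligible)) stop("no combination dose reached steady state", call. = FALSE)
  # order: lowest LT3 first, then lowest LT4, so ties resolve conservatively
  ord <- order(sweep$lt3, sweep$lt4)
  cand <- sweep[ord, ][eligible[ord], ]
  best <- cand[which.min(cand$score), ]
  structure(list(lt4 = best$lt4, lt3 = best$lt3, schedule = schedule,
                 rtf = rtf, sweep = sweep, score = best$score),
            class = "dose_search")
}

#' Dose prediction accuracy
#'
#' A predicted dose counts as correct when it lies within 12.5 ug (one
#' tablet increment, boundary inclusive) of the empirically determined dose.
#'
#' @param predicted,empirical Daily doses, ug (>= 0); vectors recycle.
#' @param tol Accuracy tolerance, ug (default 12.5).
#' @return Logical vector.
#' @export
dose_accuracy <- function(predicted, empirical, tol = 12.5) {
  if (any(predicted < 0) || any(empirical < 0))
    stop("doses must be non-negative", call. = FALSE)
  abs(predicted - empirical) <= tol
}

#' Cohort dose accuracy by BMI bin
#'
#' Scores predicted against empirical doses and reports the proportion
#' correct overall and within the BMI bins `<= 26`, `(26, 32)` and `>= 32`.
#' Empty bins are reported as `NA`.
#'
#' @param cohort Data frame with columns `predicted`, `empirical`, `bmi`.
#' @param tol Accuracy tolerance, ug.
#' @return List with `overall` proportion and `by_bin` named vector.
#' @export
cohort_accuracy <- function(cohort, tol = 12.5) {
  stopifnot(all(c("predicted", "empirical", "bmi") %in% names(cohort)))
  ok <- dose_accuracy(cohort$predicted, cohort$empirical, tol)
  bin <- cut(cohort$bmi, c(-Inf, 26, 32 - 1e-9, Inf),
             labels = c("BMI<=26", "26<BMI<32", "BMI>=32"), right = TRUE)
  by_bin <- vapply(levels(bin), function(b) {
    idx <- bin == b
    if (!any(idx)) NA_real_ else mean(ok[idx])
  }, numeric(1))
  list(overall = mean(ok), by_bin = by_bin, n = nrow(cohort))
}

#' Combination-therapy scenario grid
#'
#' The 18 canonical combination-therapy scenarios: male and female patients
#' (fixed heights 1.78 / 1.63 m) at three BMI classes -- underweight (18.5),
#' normal (23) and overweight (27.5, the midpoint of the 25--30 class) --
#' under three schedules with their conventional residual thyroid function
#' pairings: once-daily dosing at RTF 10%, twice-daily at 15%, and
#' once-daily LT4 plus constant T3 infusion at 25%.
#'
#' @return Data frame with `sex`, `bmi_class`, `bmi`, `height_m`,
#'   `weight_kg`, `schedule`, `rtf` (18 rows).
#' @export
combo_scenarios <- function() {
  g <- expand.grid(
    sex = c("male", "female"),
    bmi_class = c("underweight", "normal", "overweight"),
    schedule = c("daily", "twice_daily", "infusion"),
    stringsAsFactors = FALSE)
  g$bmi <- c(underweight = 18.5, normal = 23, overweight = 27.5)[g$bmi_class]
  g$height_m <- ifelse(g$sex == "male", 1.78, 1.63)
  g$weight_kg <- g$bmi * g$height_m^2
  g$rtf <- c(daily = 0.10, twice_daily = 0.15, infusion = 0.25)[g$schedule]
  g[, c("sex", "bmi_class", "bmi", "height_m", "weight_kg", "schedule", "rtf")]
}

#' Run the combination-therapy scenario sweep
#'
#' Applies [optimize_combo()] to each row of a scenario grid (default
#' [combo_scenarios()]) and collects the optimized daily LT4 and LT3 doses.
#'
#' @param scenarios Scenario data frame as from [combo_scenarios()].
#' @inheritParams optimize_combo
#' @param verbose Print one line per scenario as it completes.
#' @return The scenario data frame with `lt4`, `lt3` (ug/day) and `score`
#'   columns appended.
#' @export
run_combo_scenarios <- function(scenarios = combo_scenarios(),
                                grid_lt4 = seq(62.5, 325, by = 12.5),
                                grid_lt3 = lt3_grid(),
                                ranges = normal_ranges(), days = 50,
                                params = hpt_params(), verbose = FALSE) {
  res <- lapply(seq_len(nrow(scenarios)), function(i) {
    s <- scenarios[i, ]
    pt <- patient_profile(s$sex, s$height_m, s$weight_kg)
    fit <- optimize_combo(pt, rtf = s$rtf, schedule = s$schedule,
                          grid_lt4 = grid_lt4, grid_lt3 = grid_lt3,
                          ranges = ranges, days = days, params = params)
    if (verbose)
      message(sprintf("%-6s %-11s %-12s rtf %.2f -> LT4 %5.1f LT3 %4.1f",
                      s$sex, s$bmi_class, s$schedule, s$rtf, fit$lt4, fit$lt3))
    c(lt4 = fit$lt4, lt3 = fit$lt3, score = fit$score)
  })
  cbind(scenarios, do.call(rbind, res))
}
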