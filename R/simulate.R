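#' Dose regimen
#'
#' A periodic oral replacement regimen: `lt4` and `lt3` are the amounts (ug)
#' given *per administration* every `interval` hours; `t3_infusion` is a
#' constant intravenous T3 rate in ug/h (emulating slow-release
#' preparations). `duration` (days) is optional and used as the default
#' simulation length.
#'
#' @param lt4,lt3 Oral dose per administration, ug (>= 0).
#' @param interval Dosing interval in hours; 24 = once daily, 12 = twice
#'   daily (other positive values allowed).
#' @param t3_infusion Constant T3 infusion rate, ug/h (>= 0).
#' @param duration Optional regimen duration in days.
#' @return Object of class `dose_regimen`.
#' @examples
#' dose_regimen(lt4 = 112.5)                      # once-daily LT4
#' dose_regimen(lt4 = 50, lt3 = 2.5, interval = 12) # twice-daily combination
#' @export
dose_regimen <- function(lt4 = 0, lt3 = 0, interval = 24, t3_infusion = 0,
                         duration = NULL) {
  stopifnot(is.numeric(lt4), length(lt4) == 1L, lt4 >= 0,
            is.numeric(lt3), length(lt3) == 1L, lt3 >= 0,
            is.numeric(interval), length(interval) == 1L, interval > 0,
            is.numeric(t3_infusion), length(t3_infusion) == 1L, t3_infusion >= 0)
  if (!is.null(duration)) stopifnot(is.numeric(duration), duration > 0)
  structure(list(lt4 = lt4, lt3 = lt3, interval = interval,
                 t3_infusion = t3_infusion, duration = duration),
            class = "dose_regimen")
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("<dose_regimen> LT4 %g ug + LT3 %g ug every %g h; infusion %g ug/h\n",
              x$lt4, x$lt3, x$interval, x$t3_infusion))
  invisible(x)
}

# molecular weights used to convert dose mass to model amounts
.MW_T4 <- 777   # ug/umol
.MW_T3 <- 651
.TSH_CONV <- 5.6  # mU per model TSH amount unit

# nominal state used to seed steady-state searches
.nominal_state <- c(0.322, 0.201, 0.639, 0.00663, 0.0113, 0.0653, 1.78,
                    7.05, 7.05, 0, 0, 0, 0, 3.34, 3.69, 3.88, 3.90, 3.78, 3.55)

#' Convert compartment amounts to clinical concentrations
#'
#' Plasma amounts divided by the (personalized) distribution volumes and
#' scaled to clinical units: T4 and T3 in ug/L (molecular weights 777 and 651
#' ug/umol over `Vp`), TSH in mU/L (over `Vtsh`).
#'
#' @param state Numeric state vector (length 19) or matrix with 19 columns.
#' @param params An [hpt_params()] set.
#' @return Named vector (or matrix) with `t4_ugL`, `t3_ugL`, `tsh_mUL`.
#' @export
to_concentrations <- function(state, params) {
  vp <- params[["Vp"]]; vtsh <- params[["Vtsh"]]
  if (is.matrix(state)) {
    cbind(t4_ugL = .MW_T4 * state[, 1] / vp,
          t3_ugL = .MW_T3 * state[, 4] / vp,
          tsh_mUL = .TSH_CONV * state[, 7] / vtsh)
  } else {
    c(t4_ugL = .MW_T4 * state[[1]] / vp,
      t3_ugL = .MW_T3 * state[[4]] / vp,
      tsh_mUL = .TSH_CONV * state[[7]] / vtsh)
  }
}

# inverse of to_concentrations for the plasma compartments (used in tests)
from_concentrations <- function(conc, params) {
  c(T4_plasma = conc[["t4_ugL"]] * params[["Vp"]] / .MW_T4,
    T3_plasma = conc[["t3_ugL"]] * params[["Vp"]] / .MW_T3,
    TSH_plasma = conc[["tsh_mUL"]] * params[["Vtsh"]] / .TSH_CONV)
}

#' Euthyroid initial condition
#'
#' Computes the circadian-cycle-averaged euthyroid steady state of the
#' personalized model (thyroidal secretion intact, no dosing): the model is
#' integrated with the oscillatory term averaged out until stationary, then
#' the state is polished to an algebraic root of the averaged right-hand
#' side.
#'
#' @param params An [hpt_params()] set; `rtf` is forced to 1 and dosing off
#'   for the computation.
#' @param guess Optional starting state (length 19).
#' @param tol Residual norm required of the root (umol/h scale).
#' @return Named steady-state vector of length 19.
#' @export
initial_condition <- function(params, guess = NULL, tol = 1e-8) {
  p <- params
  p[["rtf"]] <- 1; p[["infusion"]] <- 0; p[["circadian"]] <- 0
  y0 <- if (is.null(guess)) .nominal_state else unname(guess)
  out <- integrate_model(p, y0, times = c(0, 2400, 4800, 7200),
                         rtol = 1e-10, atol = 1e-12)
  y <- out[nrow(out), 1 + seq_len(19)]
  fn <- function(q) hpt_rhs(0, q, p)[[1]]
  root <- tryCatch(pracma::broyden(fn, unname(y), maxiter = 50, tol = 1e-12),
                   error = function(e) NULL)
  if (!is.null(root) && all(is.finite(root$zero)) && min(root$zero) > -1e-10)
    y <- pmax(root$zero, 0)
  res <- sqrt(sum(fn(y)^2))
  if (res > tol)
    stop("initial_condition failed to converge: residual norm ", signif(res, 3),
         call. = FALSE)
  stats::setNames(unname(y), .state_names)
}

# low-level integrator wrapper (compiled RHS by default)
integrate_model <- function(params, y0, times, events = NULL,
                            rtol = 1e-6, atol = 1e-9, compiled = TRUE,
                            maxsteps = 50000) {
  y0 <- stats::setNames(unname(y0), .state_names)
  if (compiled) {
    out <- deSolve::ode(y = y0, times = times, func = "hpt_derivs",
                        parms = pack_parms(params), dllname = "hptsim",
                        initfunc = "hpt_initparms", method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = maxsteps,
                        events = events)
  } else {
    out <- deSolve::ode(y = y0, times = times, func = hpt_rhs, parms = params,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = maxsteps, events = events)
  }
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (istate = ", attr(out, "istate")[1],
         "); last state: ",
         paste(signif(out[nrow(out), -1], 4), collapse = " "), call. = FALSE)
  st <- out[, -1, drop = FALSE]
  if (min(st) < -1e-6)
    stop("integration produced a significantly negative amount (min ",
         signif(min(st), 3), ")", call. = FALSE)
  out
}

# dose administration times for a regimen over `days`
dose_times <- function(regimen, days) {
  seq(0, days * 24 - 1e-9, by = regimen$interval)
}

# deSolve event table adding pill boluses to the dissolution compartments
dose_events <- function(regimen, days) {
  tt <- dose_times(regimen, days)
  ev <- NULL
  if (regimen$lt4 > 0)
    ev <- rbind(ev, data.frame(var = 10, time = tt,
                               value = regimen$lt4 / .MW_T4, method = "add"))
  if (regimen$lt3 > 0)
    ev <- rbind(ev, data.frame(var = 12, time = tt,
                               value = regimen$lt3 / .MW_T3, method = "add"))
  if (is.null(ev)) return(NULL)
  ev[order(ev$time, ev$var), ]
}

#' Simulate a treatment course
#'
#' Integrates the personalized model under a dosing regimen: oral doses are
#' bit-exact boluses added to the pill compartments at each administration
#' time (integration stops and restarts at dose events), constant T3
#' infusion enters the plasma T3 compartment continuously.
#'
#' @param params Personalized [hpt_params()]; set `rtf` via [apply_rtf()]
#'   beforehand (e.g. 0 for complete thyroidectomy).
#' @param regimen A [dose_regimen()].
#' @param days Simulation length in days (default `regimen$duration`, else 42).
#' @param init Initial state; default [initial_condition()] of `params` with
#'   intact thyroid (post-thyroidectomy onset at t = 0 when `rtf < 1`).
#' @param sample_by Output sampling interval, hours (<= 1 h recommended).
#' @param rtol,atol Solver tolerances (stiff-capable lsoda).
#' @param compiled Use the compiled RHS (default) or the R reference RHS.
#' @return An `hpt_trajectory`: data frame with `time_h`, `t4_ugL`, `t3_ugL`,
#'   `tsh_mUL`, with the full state history in attribute `"state"`.
#' @examples
#' \donttest{
#' p <- personalize(hpt_params(), patient_profile("female", 1.67, 63))
#' tr <- run_course(apply_rtf(p, 0), dose_regimen(lt4 = 112.5), days = 7)
#' head(tr)
#' }
#' @export
run_course <- function(params, regimen = dose_regimen(), days = NULL,
                       init = NULL, sample_by = 1, rtol = 1e-6, atol = 1e-9,
                       compiled = TRUE) {
  stopifnot(inherits(regimen, "dose_regimen"))
  if (is.null(days)) days <- if (!is.null(regimen$duration)) regimen$duration else 42
  stopifnot(days > 0)
  p <- params
  p[["infusion"]] <- regimen$t3_infusion / .MW_T3  # ug/h -> umol/h
  if (is.null(init)) init <- initial_condition(params)
  times <- sort(unique(c(seq(0, days * 24, by = sample_by), days * 24,
                         dose_times(regimen, days))))
  ev <- dose_events(regimen, days)
  out <- integrate_model(p, init, times,
                         events = if (!is.null(ev)) list(data = ev),
                         rtol = rtol, atol = atol, compiled = compiled)
  state <- out[, 1 + seq_len(19), drop = FALSE]
  colnames(state) <- .state_names
  conc <- to_concentrations(state, p)
  traj <- data.frame(time_h = out[, 1], conc)
  attr(traj, "state") <- state
  attr(traj, "params") <- p
  class(traj) <- c("hpt_trajectory", "data.frame")
  traj
}

#' Steady state under a periodic regimen
#'
#' Runs the model for `days` (default 50) under a periodic (or empty)
#' regimen and summarizes the final day: the final-time concentrations, the
#' final-day means, and a convergence flag comparing the last two daily
#' means (non-convergence, relative difference > 0.5%, sets
#' `converged = FALSE` with a warning rather than an error).
#'
#' @inheritParams run_course
#' @param days Days to integrate (default 50).
#' @param warn Warn on non-convergence (default TRUE).
#' @return List with `final` and `day_mean` (named concentration triples),
#'   `converged`, and `rel_change` (max relative change between the last two
#'   daily means).
#' @export
steady_state <- function(params, regimen = dose_regimen(), days = 50,
                         init = NULL, rtol = 1e-6, atol = 1e-9,
                         compiled = TRUE, warn = TRUE) {
  stopifnot(days >= 2)
  p <- params
  p[["infusion"]] <- regimen$t3_infusion / .MW_T3
  if (is.null(init)) init <- initial_condition(params)
  times <- sort(unique(c(0, dose_times(regimen, days),
                         seq((days - 2) * 24, days * 24, by = 0.5))))
  ev <- dose_events(regimen, days)
  out <- integrate_model(p, init, times,
                         events = if (!is.null(ev)) list(data = ev),
                         rtol = rtol, atol = atol, compiled = compiled)
  tt <- out[, 1]
  conc <- to_concentrations(out[, 1 + seq_len(19), drop = FALSE], p)
  last <- tt >= (days - 1) * 24
  prev <- tt >= (days - 2) * 24 & tt < (days - 1) * 24
  m_last <- colMeans(conc[last, , drop = FALSE])
  m_prev <- colMeans(conc[prev, , drop = FALSE])
  # relative change with an absolute floor per channel (a small fraction of
  # the clinical scale of each hormone) so that concentrations decaying
  # toward zero (e.g. T4 after thyroidectomy) are not flagged forever
  floor <- c(t4_ugL = 10, t3_ugL = 0.2, tsh_mUL = 0.1)
  rel <- max(abs(m_last - m_prev) / pmax(abs(m_prev), floor))
  converged <- rel <= 0.005
  if (!converged && warn)
    warning("steady_state: last two daily means differ by ",
            signif(100 * rel, 3), "% (> 0.5%)", call. = FALSE)
  list(final = conc[nrow(conc), ], day_mean = m_last,
       converged = converged, rel_change = rel)
}

#' Export a trajectory as tidy CSV
#'
#' Writes `time_h, t4_ugL, t3_ugL, tsh_mUL` with provenance comment lines.
#'
#' @param traj An `hpt_trajectory` from [run_course()].
#' @param path Output file.
#' @param meta Optional named list recorded in the header comments.
#' @export
write_trajectory <- function(traj, path, meta = NULL) {
  stopifnot(inherits(traj, "hpt_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# hptsim trajectory; config: ",
                    jsonlite::toJSON(meta %||% list(), auto_unbox = TRUE)), con)
  utils::write.csv(as.data.frame(traj)[, c("time_h", "t4_ugL", "t3_ugL", "tsh_mUL")],
                   con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
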