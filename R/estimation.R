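#' Hormone observation table
#'
#' Observations for maximum-likelihood fitting: one row per measurement with
#' `channel` (`"T4"`, `"T3"` or `"TSH"`), `time_h`, `value`, and an optional
#' per-observation `weight` multiplier (default 1).
#'
#' @param channel Character vector of channels.
#' @param time_h Non-negative measurement times, hours.
#' @param value Non-negative measured concentrations (T4/T3 in ug/L, TSH in
#'   mU/L).
#' @param weight Positive weights (recycled).
#' @return Data frame of class `hormone_obs`.
#' @export
hormone_obs <- function(channel, time_h, value, weight = 1) {
  channel <- toupper(as.character(channel))
  if (!all(channel %in% c("T4", "T3", "TSH")))
    stop("`channel` must be T4, T3 or TSH", call. = FALSE)
  if (any(time_h < 0)) stop("`time_h` must be non-negative", call. = FALSE)
  if (any(value < 0)) stop("`value` must be non-negative", call. = FALSE)
  weight <- rep_len(weight, length(value))
  if (any(weight <= 0)) stop("`weight` must be positive", call. = FALSE)
  structure(data.frame(channel = channel, time_h = time_h, value = value,
                       weight = weight),
            class = c("hormone_obs", "data.frame"))
}

#' Gaussian negative log-likelihood of hormone observations
#'
#' Independent-Gaussian likelihood per channel with channel-specific
#' standard deviations: for each channel,
#' `N log(2 pi) / 2 + N log(sigma) + sum_j w_j (y_j - mu_j)^2 / (2 sigma^2)`
#' with effective count `N = sum_j w_j`, summed over channels (additive).
#' Observation weights generalize point replication; at weight 1 this is the
#' classical expression.
#'
#' @param obs A [hormone_obs()] table.
#' @param pred Predicted means, aligned with the rows of `obs`.
#' @param sigmas Named positive vector with entries for each channel present
#'   (e.g. `c(T4 = 5, T3 = 0.1, TSH = 0.3)`).
#' @return Scalar negative log-likelihood.
#' @export
neg_loglik <- function(obs, pred, sigmas) {
  stopifnot(inherits(obs, "hormone_obs") || is.data.frame(obs))
  if (length(pred) != nrow(obs))
    stop("`pred` must align with the rows of `obs`", call. = FALSE)
  total <- 0
  for (ch in unique(obs$channel)) {
    s <- sigmas[[ch]]
    if (is.null(s) || !is.finite(s) || s <= 0)
      stop("`sigmas` must supply a positive value for channel ", ch,
           call. = FALSE)
    i <- obs$channel == ch
    w <- obs$weight[i]
    n_eff <- sum(w)
    r2 <- sum(w * (obs$value[i] - pred[i])^2)
    total <- total + n_eff * log(2 * pi) / 2 + n_eff * log(s) + r2 / (2 * s^2)
  }
  total
}

# closed-form per-channel MLE of sigma (weighted RMS residual)
profile_sigmas <- function(obs, pred, floor = 1e-12) {
  vapply(split(seq_len(nrow(obs)), obs$channel), function(i) {
    w <- obs$weight[i]
    max(sqrt(sum(w * (obs$value[i] - pred[i])^2) / sum(w)), floor)
  }, numeric(1))
}

#' Emphasize selected TSH observations
#'
#' Multiplies the weight (default) or the value of the listed TSH
#' observations by `factor` (default 100), leaving all others unchanged.
#' Used to make the optimizer track the circadian extremes of the TSH
#' trajectory: the canonical choice scales the 9th, 13th, 24th and 28th TSH
#' observations (the two highest and two lowest of the initial trajectory)
#' by 100.
#'
#' @param obs A [hormone_obs()] table.
#' @param indices Positions *within the TSH observations* (in row order) to
#'   scale; default `c(9, 13, 24, 28)`.
#' @param factor Multiplier (default 100).
#' @param mode `"weight"` (default) or `"value"`.
#' @return The modified observation table.
#' @export
scale_tsh_points <- function(obs, indices = c(9, 13, 24, 28), factor = 100,
                             mode = c("weight", "value")) {
  mode <- match.arg(mode)
  tsh_rows <- which(obs$channel == "TSH")
  if (any(indices < 1 | indices > length(tsh_rows)))
    stop("`indices` out of range: only ", length(tsh_rows),
         " TSH observations present", call. = FALSE)
  rows <- tsh_rows[indices]
  if (mode == "weight") obs$weight[rows] <- obs$weight[rows] * factor
  else obs$value[rows] <- obs$value[rows] * factor
  obs
}

#' Experimental design for a fitting protocol
#'
#' Describes how a hormone time-course dataset was generated: oral dose
#' events, optional constant T3 infusion, residual thyroid function, and the
#' duration. The canonical euthyroid challenge protocol gives a single oral
#' LT4 dose (400, 450 or 600 ug) at hour 24 of a 5-day course.
#'
#' @param t4_events,t3_events Data frames with `time_h` and `dose_ug`
#'   columns (or `NULL`).
#' @param duration_h Protocol duration, hours.
#' @param rtf Residual thyroid function during the protocol.
#' @param t3_infusion Constant T3 infusion, ug/h.
#' @return List of class `fit_design`.
#' @export
fit_design <- function(t4_events = NULL, t3_events = NULL, duration_h = 120,
                       rtf = 1, t3_infusion = 0) {
  chk <- function(ev, nm) {
    if (is.null(ev)) return(NULL)
    stopifnot(all(c("time_h", "dose_ug") %in% names(ev)))
    if (any(ev$time_h < 0) || any(ev$dose_ug < 0))
      stop("`", nm, "` must have non-negative times and doses", call. = FALSE)
    ev
  }
  structure(list(t4_events = chk(t4_events, "t4_events"),
                 t3_events = chk(t3_events, "t3_events"),
                 duration_h = duration_h, rtf = rtf,
                 t3_infusion = t3_infusion),
            class = "fit_design")
}

#' @rdname fit_design
#' @param dose_ug Oral LT4 challenge dose, ug.
#' @param dose_time Administration time, hours.
#' @export
euthyroid_challenge <- function(dose_ug, dose_time = 24, duration_h = 120) {
  fit_design(t4_events = data.frame(time_h = dose_time, dose_ug = dose_ug),
             duration_h = duration_h)
}

# model predictions at the observation times of one design
simulate_design <- function(params, design, obs, init = NULL,
                            rtol = 1e-6, atol = 1e-9) {
  p <- params
  p[["rtf"]] <- design$rtf
  p[["infusion"]] <- design$t3_infusion / .MW_T3
  if (is.null(init)) init <- initial_condition(params)
  ev <- NULL
  if (!is.null(design$t4_events) && nrow(design$t4_events))
    ev <- rbind(ev, data.frame(var = 10, time = design$t4_events$time_h,
                               value = design$t4_events$dose_ug / .MW_T4,
                               method = "add"))
  if (!is.null(design$t3_events) && nrow(design$t3_events))
    ev <- rbind(ev, data.frame(var = 12, time = design$t3_events$time_h,
                               value = design$t3_events$dose_ug / .MW_T3,
                               method = "add"))
  if (!is.null(ev)) ev <- ev[order(ev$time, ev$var), ]
  times <- sort(unique(c(0, obs$time_h, ev$time, design$duration_h)))
  out <- integrate_model(p, init, times,
                         events = if (!is.null(ev)) list(data = ev),
                         rtol = rtol, atol = atol)
  conc <- to_concentrations(out[, 1 + seq_len(19), drop = FALSE], p)
  col <- c(T4 = "t4_ugL", T3 = "t3_ugL", TSH = "tsh_mUL")
  idx <- match(obs$time_h, out[, 1])
  conc[cbind(idx, match(col[obs$channel], colnames(conc)))]
}

#' Maximum-likelihood parameter fitting
#'
#' Minimizes the Gaussian negative log-likelihood of one or more hormone
#' datasets over a chosen subset of model parameters with the gradient-free
#' Nelder-Mead simplex. The channel standard deviations are profiled out in
#' closed form at every evaluation (their MLE is the weighted RMS residual,
#' which is also the stationarity condition of the likelihood in sigma), and
#' the search runs on log-transformed parameters to enforce positivity.
#' Simulation failures during the search are penalized, not fatal. The
#' search is deterministic given `init`, `seed` and solver settings; a fixed
#' number of deterministically perturbed restarts guards against simplex
#' stagnation.
#'
#' @param obs A [hormone_obs()] table or list of tables (one per dataset).
#' @param designs A [fit_design()] or list matching `obs`.
#' @param free Character vector of parameter names to estimate (subset of
#'   the estimable set; see Details). Empty `free` returns `init`/defaults
#'   unchanged.
#' @param init Named numeric starting values (defaults to the current
#'   `params` values of `free`).
#' @param params Base [hpt_params()] (personalized if appropriate).
#' @param restarts Number of perturbed restarts after the first search.
#' @param perturb Relative size of restart perturbations.
#' @param seed Seed for the deterministic restart perturbations.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param compute_cvs Also compute inverse-Hessian %CVs ([parameter_cvs()]).
#' @param rtol,atol Solver tolerances used in every simulation.
#' @return List of class `hpt_fit`: `estimates`, `sigmas`, `nll`,
#'   `convergence`, `n_obs`, `cv_pct` (if requested), and the objective
#'   closure `objective` (natural scale) for diagnostics.
#' @export
fit_parameters <- function(obs, designs, free, init = NULL,
                           params = hpt_params(), restarts = 3,
                           perturb = 0.1, seed = 1L, maxit = 400,
                           compute_cvs = FALSE, rtol = 1e-6, atol = 1e-9) {
  if (inherits(obs, "hormone_obs")) obs <- list(obs)
  if (inherits(designs, "fit_design")) designs <- list(designs)
  stopifnot(length(obs) == length(designs))
  allowed <- c(.estimable_parms)
  bad <- setdiff(free, allowed)
  if (length(bad))
    stop("not estimable: ", paste(bad, collapse = ", "), call. = FALSE)
  base_init <- initial_condition(params)

  predict_all <- function(p) {
    lapply(seq_along(obs), function(i)
      simulate_design(p, designs[[i]], obs[[i]], init = base_init,
                      rtol = rtol, atol = atol))
  }
  objective <- function(theta) {
    p <- params
    p[free] <- theta
    ok <- tryCatch({ validate_params(unclass(p)); TRUE },
                   error = function(e) FALSE)
    if (!ok) return(1e10)
    preds <- tryCatch(predict_all(p), error = function(e) NULL)
    if (is.null(preds)) return(1e10)
    total <- 0
    for (i in seq_along(obs)) {
      s <- profile_sigmas(obs[[i]], preds[[i]])
      total <- total + neg_loglik(obs[[i]], preds[[i]], s)
    }
    if (!is.finite(total)) 1e10 else total
  }

  if (length(free) == 0L) {
    return(structure(list(estimates = numeric(0), sigmas = NULL,
                          nll = objective(numeric(0)), convergence = 0L,
                          objective = objective),
                     class = "hpt_fit"))
  }
  th0 <- if (is.null(init)) unclass(params)[free] else {
    stopifnot(all(free %in% names(init)))
    init[free]
  }
  obj_log <- function(lt) objective(exp(lt))
  starts <- list(log(unname(th0)))
  if (restarts > 0) {
    rng <- make_rng(seed)
    for (k in seq_len(restarts))
      starts[[k + 1]] <- log(unname(th0)) +
        perturb * (2 * rng(length(th0)) - 1)
  }
  best <- NULL
  for (s in starts) {
    fit <- if (length(th0) == 1L) {
      o <- stats::optim(s, obj_log, method = "Brent",
                        lower = s - 3, upper = s + 3)
      o
    } else {
      stats::optim(s, obj_log, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  est <- stats::setNames(exp(best$par), free)
  p_hat <- params
  p_hat[free] <- est
  preds <- predict_all(p_hat)
  sig <- lapply(seq_along(obs), function(i) profile_sigmas(obs[[i]], preds[[i]]))
  out <- structure(list(estimates = est, sigmas = sig, nll = best$value,
                        convergence = best$convergence,
                        n_obs = sum(vapply(obs, nrow, integer(1))),
                        objective = objective),
                   class = "hpt_fit")
  if (compute_cvs) out$cv_pct <- parameter_cvs(objective, est)
  out
}

#' @export
print.hpt_fit <- function(x, ...) {
  cat("<hpt_fit> nll =", signif(x$nll, 6), "\n")
  if (length(x$estimates)) print(signif(x$estimates, 4))
  invisible(x)
}

#' Parameter variability from the inverse Hessian
#'
#' Percent coefficients of variation for maximum-likelihood estimates: the
#' numerical Hessian of the negative log-likelihood at the optimum is
#' inverted to estimate the covariance matrix, and
#' `%CV = 100 * sqrt(diag(H^-1)) / estimate`. A non-positive-definite
#' Hessian yields `NA` for the affected parameters with a warning.
#'
#' @param objective Function of the free-parameter vector (natural scale)
#'   returning the negative log-likelihood, or an `hpt_fit` (its stored
#'   objective is used).
#' @param estimates Named vector of estimates at the optimum.
#' @param h Relative step for the finite-difference Hessian.
#' @return Named vector of %CVs.
#' @export
parameter_cvs <- function(objective, estimates, h = 1e-4) {
  if (inherits(objective, "hpt_fit")) {
    estimates <- objective$estimates
    objective <- objective$objective
  }
  est <- as.numeric(estimates)
  s <- pmax(abs(est), 1e-8)  # per-parameter scale for the finite differences
  g <- function(z) objective(est + z * s)
  H <- pracma::hessian(g, rep(0, length(est)), h = h)
  cv <- rep(NA_real_, length(est))
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov)) {
    warning("Hessian is singular; %CVs unavailable", call. = FALSE)
  } else {
    v <- diag(cov) * s^2  # back to the natural parameter scale
    ok <- is.finite(v) & v > 0
    if (!all(ok))
      warning("Hessian not positive definite for some parameters; ",
              "affected %CVs set to NA", call. = FALSE)
    cv[ok] <- 100 * sqrt(v[ok]) / abs(est[ok])
  }
  stats::setNames(cv, names(estimates))
}

#' Calibrate B0 against a maximum TSH plateau
#'
#' The mean TSH secretion rate `B0` sets the plateau TSH concentration
#' reached by an untreated, completely athyreotic patient. Individual data
#' rarely pin this plateau down (assay dilution ceilings), so it is fixed by
#' choice of a plausible maximum TSH (e.g. 300, 500, 750 or 1000 mU/L) and
#' `B0` is adjusted until the simulated 50-day thyroidectomy plateau matches.
#'
#' @param max_tsh Desired plateau TSH, mU/L.
#' @param params Base [hpt_params()].
#' @param days Days simulated to reach the plateau.
#' @param tol Relative tolerance on the plateau match.
#' @return The calibrated parameter set (element `B0` adjusted), with the
#'   achieved plateau in attribute `"plateau"`.
#' @export
calibrate_b0 <- function(max_tsh, params = hpt_params(), days = 50,
                         tol = 1e-4) {
  stopifnot(max_tsh > 0)
  plateau <- function(b0) {
    p <- params
    p[["B0"]] <- b0
    # keep the circadian mean consistent if A0 would exceed the new mean
    p[["A0"]] <- min(params[["A0"]], b0)
    ss <- steady_state(apply_rtf(p, 0), days = days,
                       init = initial_condition(p), warn = FALSE)
    ss$day_mean[["tsh_mUL"]]
  }
  # the plateau is nearly proportional to B0: secant iteration from default
  b0 <- params[["B0"]]
  for (i in 1:8) {
    got <- plateau(b0)
    if (abs(got - max_tsh) / max_tsh < tol) break
    b0 <- b0 * max_tsh / got
  }
  out <- params
  out[["B0"]] <- b0
  out[["A0"]] <- min(params[["A0"]], b0)
  attr(out, "plateau") <- got
  out
}
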