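#' Steady-state hormone curve versus residual thyroid function
#'
#' For an untreated patient, computes the 50-day steady-state plasma T4, T3
#' (ug/L) and TSH (mU/L) at each residual thyroid function (RTF) value of a
#' grid (default 0 to 0.5 in steps of 0.01). Over this range TSH decreases
#' strictly with RTF while T4 and T3 increase, so the curve is invertible
#' and provides a means of estimating a patient's unmeasurable RTF from
#' pre-treatment hormone measurements (see [estimate_rtf()]). Default curve
#' heights are 1.78 m (male) and 1.63 m (female); BMI sets the weight.
#'
#' @param sex `"male"` or `"female"`.
#' @param bmi Body mass index, kg/m^2.
#' @param height Height in meters (sex-specific default 1.78 / 1.63).
#' @param rtf_grid RTF fractions in \[0, 1\].
#' @param params Reference [hpt_params()].
#' @param days Days to steady state per grid point (default 50).
#' @param rtol,atol Solver tolerances.
#' @return Data frame of class `rtf_curve` with columns `rtf`, `t4_ugL`,
#'   `t3_ugL`, `tsh_mUL`, `converged`; the patient is kept in attribute
#'   `"patient"`. Non-convergent grid points are flagged, not dropped.
#' @examples
#' \donttest{
#' rc <- rtf_curve("female", bmi = 25, rtf_grid = seq(0, 0.5, 0.1))
#' }
#' @export
rtf_curve <- function(sex, bmi, height = NULL,
                      rtf_grid = seq(0, 0.5, by = 0.01),
                      params = hpt_params(), days = 50,
                      rtol = 1e-6, atol = 1e-9) {
  sex <- match_sex(sex)
  if (is.null(height)) height <- if (sex == "male") 1.78 else 1.63
  if (any(rtf_grid < 0 | rtf_grid > 1))
    stop("`rtf_grid` values must lie in [0, 1]", call. = FALSE)
  rtf_grid <- sort(rtf_grid)
  patient <- patient_profile(sex, height, bmi * height^2)
  pp <- personalize(params, patient)
  init <- initial_condition(pp)
  rows <- lapply(rtf_grid, function(r) {
    ss <- tryCatch(
      steady_state(apply_rtf(pp, r), days = days, init = init,
                   rtol = rtol, atol = atol, warn = FALSE),
      error = function(e) NULL)
    if (is.null(ss))
      return(data.frame(rtf = r, t4_ugL = NA_real_, t3_ugL = NA_real_,
                        tsh_mUL = NA_real_, converged = FALSE))
    m <- ss$day_mean
    data.frame(rtf = r, t4_ugL = m[["t4_ugL"]], t3_ugL = m[["t3_ugL"]],
               tsh_mUL = m[["tsh_mUL"]], converged = ss$converged)
  })
  out <- do.call(rbind, rows)
  attr(out, "patient") <- patient
  class(out) <- c("rtf_curve", "data.frame")
  out
}

# monotone piecewise-cubic inverse of one hormone channel; preserves the
# invertibility guaranteed by the curve's monotonicity
channel_inverse <- function(curve, channel) {
  x <- curve[[channel]]
  r <- curve$rtf
  ok <- is.finite(x)
  x <- x[ok]; r <- r[ok]
  if (length(x) < 2L) stop("curve has too few valid points", call. = FALSE)
  d <- diff(x)
  if (!all(d > 0) && !all(d < 0))
    stop("curve channel `", channel, "` is not monotone; cannot invert ",
         "(failed curve)", call. = FALSE)
  list(fn = stats::splinefun(x, r, method = "monoH.FC"),
       lo = min(x), hi = max(x),
       r_at_lo = r[which.min(x)], r_at_hi = r[which.max(x)])
}

#' Estimate residual thyroid function from hormone measurements
#'
#' Inverts an [rtf_curve()] at observed pre-treatment hormone values. With a
#' single hormone the monotone piecewise-cubic interpolant of the curve is
#' inverted directly; with several, the least-squares-consistent RTF (the
#' value minimizing the sum of squared normalized deviations of the curve
#' from the observations) is returned along with the per-channel estimates.
#' Observations outside the curve's range are clamped to the corresponding
#' boundary with a warning.
#'
#' @param observed Named vector with any of `t4_ugL`, `t3_ugL`, `tsh_mUL`
#'   (aliases `t4`, `t3`, `tsh` accepted).
#' @param curve An [rtf_curve()].
#' @return List with `rtf` (consensus estimate), `per_channel` (named
#'   vector), and `clamped` (logical per channel).
#' @export
estimate_rtf <- function(observed, curve) {
  stopifnot(inherits(curve, "rtf_curve"))
  nm <- names(observed)
  if (is.null(nm)) stop("`observed` must be a named vector", call. = FALSE)
  map <- c(t4 = "t4_ugL", t3 = "t3_ugL", tsh = "tsh_mUL",
           t4_ugL = "t4_ugL", t3_ugL = "t3_ugL", tsh_mUL = "tsh_mUL")
  bad <- !nm %in% names(map)
  if (any(bad))
    stop("unknown hormone name(s): ", paste(nm[bad], collapse = ", "),
         call. = FALSE)
  channels <- unname(map[nm])
  per <- numeric(0); clamped <- logical(0)
  for (i in seq_along(channels)) {
    ch <- channels[i]
    inv <- channel_inverse(curve, ch)
    v <- as.numeric(observed[[i]])
    cl <- FALSE
    if (v < inv$lo) { v <- inv$lo; cl <- TRUE }
    if (v > inv$hi) { v <- inv$hi; cl <- TRUE }
    if (cl)
      warning("observed ", ch, " outside the curve range; clamped to boundary",
              call. = FALSE)
    est <- if (v == inv$lo) inv$r_at_lo else if (v == inv$hi) inv$r_at_hi
           else min(max(inv$fn(v), min(curve$rtf)), max(curve$rtf))
    per[ch] <- est
    clamped[ch] <- cl
  }
  if (length(per) == 1L) {
    return(list(rtf = unname(per[1]), per_channel = per, clamped = clamped))
  }
  # consensus: least-squares in normalized hormone space along the curve
  interp <- lapply(channels, function(ch) {
    ok <- is.finite(curve[[ch]])
    stats::splinefun(curve$rtf[ok], curve[[ch]][ok], method = "monoH.FC")
  })
  scales <- vapply(channels, function(ch)
    max(abs(curve[[ch]]), na.rm = TRUE), numeric(1))
  obsv <- as.numeric(observed)
  ssq <- function(r) {
    pred <- vapply(interp, function(f) f(r), numeric(1))
    sum(((pred - obsv) / scales)^2)
  }
  opt <- stats::optimize(ssq, range(curve$rtf), tol = 1e-8)
  list(rtf = opt$minimum, per_channel = per, clamped = clamped)
}
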