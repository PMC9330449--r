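# State layout of the compartmental model. Amounts are in umol (TSH in the
# base model's mU-equivalent units); conversion to clinical concentrations is
# done by to_concentrations().
.state_names <- c(
  "T4_plasma", "T4_fast", "T4_slow",
  "T3_plasma", "T3_fast", "T3_slow",
  "TSH_plasma", "T3B", "T3B_lag",
  "T4_pill", "T4_gut", "T3_pill", "T3_gut",
  paste0("TSH_delay", 1:6))

#' State variable names
#'
#' The 19 compartments: plasma/fast/slow T4 and T3 pools, plasma TSH, the
#' lumped brain T3 and its lag state, pill and gut compartments for oral T4
#' and T3, and the 6-stage delay chain through which TSH drives thyroidal
#' secretion.
#'
#' @return Character vector of length 19.
#' @export
hpt_state_names <- function() .state_names

#' Circadian amplitude modulation
#'
#' Hill saturation of the circadian TSH oscillation amplitude by lagged brain
#' T3: `f_CIRC = x^n / (x^n + Kcirc^n)`. Near zero in severe hypothyroidism
#' (TSH fluctuations cease), near one at normal brain T3.
#'
#' @param t3b_lag Lagged brain T3 (umol), non-negative.
#' @param params An [hpt_params()] set.
#' @return Fraction in \[0, 1\], monotone increasing in `t3b_lag`.
#' @examples
#' circadian_modulation(3, hpt_params())  # half-saturation: 0.5
#' @export
circadian_modulation <- function(t3b_lag, params = hpt_params()) {
  if (any(t3b_lag < 0)) stop("`t3b_lag` must be non-negative", call. = FALSE)
  K <- params[["Kcirc"]]; n <- params[["n"]]
  t3b_lag^n / (t3b_lag^n + K^n)
}

#' TSH secretion rate
#'
#' The pituitary TSH secretion function: a circadian oscillation about mean
#' `B0` with amplitude `A0 * f_CIRC`, multiplied by a Hill suppressor in
#' lagged brain T3,
#' `SR_TSH = [B0 + A0 f_CIRC sin(pi t / 12 - phi)] * KSRTSH^m / (KSRTSH^m + x^m)`.
#' The oscillatory factor has a 24-h period. As brain T3 falls the rate
#' saturates at `B0` instead of growing without bound; as brain T3 rises the
#' rate is suppressed towards zero.
#'
#' @param t Time in hours (>= 0).
#' @inheritParams circadian_modulation
#' @return Secretion rate in umol/h, in `(0, B0 + A0]`.
#' @export
tsh_secretion_rate <- function(t, t3b_lag, params = hpt_params()) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  if (any(t3b_lag < 0)) stop("`t3b_lag` must be non-negative", call. = FALSE)
  K <- params[["KSRTSH"]]; m <- params[["m"]]
  osc <- params[["B0"]] + params[["A0"]] * circadian_modulation(t3b_lag, params) *
    sin(pi / 12 * t - params[["phi"]])
  osc * K^m / (K^m + t3b_lag^m)
}

#' Brain T4-to-T3 conversion gain
#'
#' Hill form of the nonlinear factor governing transport and conversion of T4
#' to T3 in brain: `f4 = k3 * (1 + 5 Kf4^l / (Kf4^l + T3B^l))`, monotone
#' decreasing from `6 k3` (empty brain T3 pool, conversion up-regulated) to
#' `k3` (saturated).
#'
#' @param t3b Lumped brain T3 (umol), non-negative.
#' @inheritParams circadian_modulation
#' @return Multiplier in `[k3, 6 k3]`.
#' @export
brain_t4_to_t3_gain <- function(t3b, params = hpt_params()) {
  if (any(t3b < 0)) stop("`t3b` must be non-negative", call. = FALSE)
  K <- params[["Kf4"]]; l <- params[["l"]]
  params[["k3"]] * (1 + 5 * K^l / (K^l + t3b^l))
}

#' Model right-hand side (reference R implementation)
#'
#' Time derivative of the 19 compartment amounts. This is the plain-R
#' transcription of the compiled RHS used by the integrator; the two are
#' tested for agreement. Volume personalization enters through the
#' concentration-equivalent amounts `x = q * V_ref / V_new` at which all
#' concentration-dependent nonlinearities are evaluated, so the regulatory
#' feedback senses concentrations; TSH secretion scales with the TSH
#' distribution volume so that the regulated TSH concentration is
#' volume-invariant. Oral and infused doses stay in amount units.
#'
#' States slightly below zero (integrator transients) are treated as zero
#' inside nonlinear terms; amounts below `-1e-6` indicate integration failure
#' and raise an error with a state dump.
#'
#' @param t Time (hours).
#' @param state Numeric vector of 19 compartment amounts.
#' @param params An [hpt_params()] set (personalized or reference).
#' @return List with the derivative vector (deSolve convention).
#' @export
hpt_rhs <- function(t, state, params) {
  if (length(state) != 19L) stop("`state` must have length 19", call. = FALSE)
  if (any(!is.finite(state)))
    stop("non-finite state in RHS at t = ", t, ": ",
         paste(signif(state, 4), collapse = " "), call. = FALSE)
  if (min(state) < -1e-6)
    stop("integration failure: negative amount at t = ", t, ": ",
         paste(signif(state, 4), collapse = " "), call. = FALSE)
  q <- pmax(state, 0)
  p <- unclass(params)
  rp <- 3.2 / p[["Vp"]]
  rt <- 5.2 / p[["Vtsh"]]
  x1 <- rp * q[1]; x4 <- rp * q[4]; x7 <- rt * q[7]

  q1F <- (p[["ftp_A"]] + p[["ftp_B"]] * x1 + p[["ftp_C"]] * x1^2 +
            p[["ftp_D"]] * x1^3) * q[1]
  q4F <- (p[["ft3_a"]] + p[["ft3_b"]] * x1 + p[["ft3_c"]] * x1^2 +
            p[["ft3_d"]] * x1^3) * q[4]
  SR4 <- p[["rtf"]] * p[["S4"]] * q[19]
  SR3 <- p[["rtf"]] * p[["S3"]] * q[19]
  fCIRC <- q[9]^p[["n"]] / (q[9]^p[["n"]] + p[["Kcirc"]]^p[["n"]])
  osc <- if (p[["circadian"]] > 0) sin(pi / 12 * t - p[["phi"]]) else 0
  SRTSH <- (p[["B0"]] + p[["A0"]] * fCIRC * osc) *
    p[["KSRTSH"]]^p[["m"]] / (p[["KSRTSH"]]^p[["m"]] + q[9]^p[["m"]])
  fdegTSH <- p[["kdegTSH"]] + p[["VmaxTSH"]] / (p[["K50TSH"]] + x7)
  fLAG <- p[["KLAG_hypo"]] + 2 * q[8]^11 / (q[8]^11 + p[["KLAG"]]^11)
  f4 <- p[["k3"]] * (1 + 5 * p[["Kf4"]]^p[["l"]] /
                       (p[["Kf4"]]^p[["l"]] + q[8]^p[["l"]]))
  NL <- p[["VmaxD1fast"]] / (p[["KmD1fast"]] + q[2])
  D1s <- p[["VmaxD1slow"]] / (p[["KmD1slow"]] + q[3])
  D2s <- p[["VmaxD2slow"]] / (p[["KmD2slow"]] + q[3])

  dq <- numeric(19)
  dq[1] <- SR4 + p[["k12"]] * q[2] + p[["k13"]] * q[3] -
    (p[["k31free"]] + p[["k21free"]]) * q1F + p[["k4absorb"]] * q[11]
  dq[2] <- p[["k21free"]] * q1F - (p[["k12"]] + p[["k02"]] + NL) * q[2]
  dq[3] <- p[["k31free"]] * q1F - (p[["k13"]] + D1s + D2s) * q[3]
  dq[4] <- SR3 + p[["k45"]] * q[5] + p[["k46"]] * q[6] -
    (p[["k64free"]] + p[["k54free"]]) * q4F + p[["k3absorb"]] * q[13] +
    p[["infusion"]]
  dq[5] <- p[["k54free"]] * q4F + NL * q[2] - (p[["k45"]] + p[["k05"]]) * q[5]
  dq[6] <- p[["k64free"]] * q4F + (D1s + D2s) * q[3] - p[["k46"]] * q[6]
  dq[7] <- SRTSH / rt - fdegTSH * q[7]
  dq[8] <- f4 / p[["T4P_eu"]] * x1 + p[["k3"]] / p[["T3P_eu"]] * x4 -
    p[["kdegT3B"]] * q[8]
  dq[9] <- fLAG * (q[8] - q[9])
  dq[10] <- -p[["k4dissolve"]] * q[10]
  dq[11] <- p[["k4dissolve"]] * q[10] - (p[["k4excrete"]] + p[["k4absorb"]]) * q[11]
  dq[12] <- -p[["k3dissolve"]] * q[12]
  dq[13] <- p[["k3dissolve"]] * q[12] - (p[["k3excrete"]] + p[["k3absorb"]]) * q[13]
  kd <- p[["kdelay"]]
  dq[14] <- -kd * q[14] + q[7]
  dq[15] <- kd * (q[14] - q[15])
  dq[16] <- kd * (q[15] - q[16])
  dq[17] <- kd * (q[16] - q[17])
  dq[18] <- kd * (q[17] - q[18])
  dq[19] <- kd * (q[18] - q[19])
  list(dq)
}
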