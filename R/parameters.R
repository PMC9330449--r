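# Canonical ordering of the dynamic parameters handed to the compiled RHS.
# Anthropometric reference parameters (BMI_*, H_*, C_M) personalize the set but
# do not enter the ODE right-hand side directly.
.ode_parm_names <- c(
  "S4", "k12", "k13", "k31free", "k21free",
  "ftp_A", "ftp_B", "ftp_C", "ftp_D",
  "k4absorb", "k02",
  "VmaxD1fast", "KmD1fast", "VmaxD1slow", "KmD1slow", "VmaxD2slow", "KmD2slow",
  "S3", "k45", "k46", "k64free", "k54free",
  "ft3_a", "ft3_b", "ft3_c", "ft3_d",
  "k3absorb", "k05",
  "B0", "A0", "phi", "kdegTSH", "VmaxTSH", "K50TSH",
  "k3", "T4P_eu", "T3P_eu", "kdegT3B", "KLAG_hypo", "KLAG",
  "k4dissolve", "k4excrete", "k3dissolve", "k3excrete",
  "Vp", "Vtsh",
  "Kcirc", "KSRTSH", "n", "m", "Kf4", "l",
  "rtf", "infusion", "circadian", "kdelay")

.anthro_parm_names <- c("BMI_Mref", "BMI_Fref", "H_Mref", "H_Fref", "C_M")

# names free for maximum-likelihood estimation (the re-estimated constants plus
# the parameters new to the personalized model)
.estimable_parms <- c(
  "S4", "VmaxD1fast", "k05", "A0", "B0", "k3", "VmaxTSH",
  "Kcirc", "KSRTSH", "n", "m", "Kf4", "l",
  "BMI_Mref", "BMI_Fref", "H_Mref", "H_Fref", "C_M")

#' Model parameter set
#'
#' Returns the full named parameter vector of the personalized
#' hypothalamic-pituitary-thyroid (HPT) axis model: base compartmental rate
#' constants, free-hormone binding polynomial coefficients, absorption and
#' dissolution rates, distribution volumes, the Hill-type TSH secretion
#' submodel constants, and the anthropometric reference parameters. Any
#' element can be overridden by name.
#'
#' Key estimated defaults: `S4 = 0.00278` (thyroidal T4 secretion
#' coefficient), `VmaxD1fast = 0.0121`, `k05 = 0.185` /h (female reference T3
#' clearance), `A0 = 220` and `B0 = 450` (circadian amplitude and mean of TSH
#' secretion, the latter fixed so untreated TSH plateaus near 1000 mU/L),
#' `k3 = 0.0589`, `VmaxTSH = 0.226`, Hill constants `Kcirc = 3`,
#' `KSRTSH = 3.1`, exponents `n = 5.68`, `m = 6.29`, `Kf4 = 8.5`, `l = 14.4`,
#' and reference anthropometry `BMI_Mref = 21.8`, `BMI_Fref = 23`,
#' `H_Mref = 1.76`, `H_Fref = 1.67`, `C_M = 1.05`.
#'
#' @param ... Named scalar overrides, e.g. `hpt_params(k05 = 0.2)`.
#' @return Named numeric vector of class `hpt_params`. Attribute `rtf` (also
#'   the `rtf` element) scales thyroidal secretion; 1 = intact gland.
#' @examples
#' p <- hpt_params()
#' p[["B0"]]
#' @export
hpt_params <- function(...) {
  p <- c(
    # thyroidal secretion (proportional to 6-stage delayed TSH)
    S4 = 0.00278, S3 = 3.3572e-4,
    # T4 plasma <-> tissue exchange and free-T4 binding polynomial
    k12 = 0.868, k13 = 0.108, k31free = 584, k21free = 1503,
    ftp_A = 0.000289, ftp_B = 0.000214, ftp_C = 0.000128, ftp_D = -8.83e-6,
    # T4 disposal and deiodination (fast/slow tissue)
    k02 = 0.0189,
    VmaxD1fast = 0.0121, KmD1fast = 2.85,
    VmaxD1slow = 6.63e-4, KmD1slow = 95,
    VmaxD2slow = 7.4619e-4, KmD2slow = 0.075,
    # T3 plasma <-> tissue exchange, free-T3 binding polynomial, clearance
    k45 = 5.37, k46 = 0.0689, k64free = 127, k54free = 2043,
    ft3_a = 0.00395, ft3_b = 0.00185, ft3_c = 0.00061, ft3_d = -0.000505,
    k05 = 0.185,
    # TSH secretion (Hill-saturated, circadian) and degradation
    B0 = 450, A0 = 220, phi = -3.71,
    Kcirc = 3, KSRTSH = 3.1, n = 5.68, m = 6.29,
    kdegTSH = 0.53, VmaxTSH = 0.226, K50TSH = 23,
    # lumped brain T3 submodel
    k3 = 0.0589, Kf4 = 8.5, l = 14.4,
    T4P_eu = 0.29, T3P_eu = 0.006, kdegT3B = 0.037,
    KLAG_hypo = 0.0034, KLAG = 5,
    # oral absorption (pill dissolution -> gut -> plasma)
    k4dissolve = 1.3, k4absorb = 0.88, k4excrete = 0.12,
    k3dissolve = 1.78, k3absorb = 0.88, k3excrete = 0.12,
    # distribution volumes (reference values; personalized per patient)
    Vp = 3.2, Vtsh = 5.2,
    # anthropometric reference parameters
    BMI_Mref = 21.8, BMI_Fref = 23, H_Mref = 1.76, H_Fref = 1.67, C_M = 1.05,
    # residual thyroid function, T3 infusion rate (umol/h), circadian switch
    rtf = 1, infusion = 0, circadian = 1, kdelay = 5 / 8)
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("overrides must be named", call. = FALSE)
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    p[names(ov)] <- as.numeric(unlist(ov))
  }
  validate_params(p)
  structure(p, class = "hpt_params")
}

validate_params <- function(p) {
  pos <- setdiff(names(p), c("ftp_D", "ft3_d", "phi", "rtf", "infusion", "circadian"))
  if (any(!is.finite(p))) stop("parameters must be finite", call. = FALSE)
  if (any(p[pos] <= 0))
    stop("parameter(s) must be positive: ",
         paste(pos[p[pos] <= 0], collapse = ", "), call. = FALSE)
  hills <- c("n", "m", "l")
  if (any(p[hills] < 1)) stop("Hill exponents must be >= 1", call. = FALSE)
  if (p[["rtf"]] < 0 || p[["rtf"]] > 1)
    stop("`rtf` must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

#' @export
print.hpt_params <- function(x, ...) {
  cat("<hpt_params> ", length(x), " parameters; Vp = ",
      signif(x[["Vp"]], 4), " L, Vtsh = ", signif(x[["Vtsh"]], 4),
      " L, k05 = ", signif(x[["k05"]], 4), " /h, rtf = ", x[["rtf"]], "\n",
      sep = "")
  invisible(x)
}

#' Personalize the model for a patient
#'
#' Substitutes the patient-specific scaled plasma volume `V_Pnew`, TSH
#' distribution volume `V_TSHnew`, and allometrically scaled T3 clearance
#' `k05_new` into the parameter set; all other parameters are unchanged.
#'
#' @param params An [hpt_params()] set (reference values).
#' @param patient An [patient_profile()] object.
#' @return Personalized `hpt_params` with attribute `"patient"`.
#' @examples
#' personalize(hpt_params(), patient_profile("female", 1.67, 64.14))
#' @export
personalize <- function(params = hpt_params(), patient) {
  stopifnot(inherits(patient, "hpt_patient"))
  vpn <- plasma_volume_scaled(patient, params)
  params[["Vp"]] <- vpn
  params[["Vtsh"]] <- tsh_distribution_volume(vpn)
  params[["k05"]] <- t3_clearance_scaled(patient, params)
  attr(params, "patient") <- patient
  params
}

#' Apply residual thyroid function
#'
#' Multiplies both thyroidal secretion terms (T4 and T3) by `rtf`; `rtf = 0`
#' is a complete thyroidectomy, `rtf = 1` leaves the model unchanged.
#'
#' @inheritParams personalize
#' @param rtf Residual thyroid function fraction in \[0, 1\].
#' @return Parameter set with the `rtf` element updated.
#' @export
apply_rtf <- function(params, rtf) {
  if (!is.numeric(rtf) || length(rtf) != 1L || !is.finite(rtf) ||
      rtf < 0 || rtf > 1)
    stop("`rtf` must be a single value in [0, 1]", call. = FALSE)
  params[["rtf"]] <- rtf
  params
}

#' Serialize / restore a parameter set
#'
#' Parameter sets round-trip losslessly through a flat key-value YAML file
#' (full double precision).
#'
#' @param params An `hpt_params` vector.
#' @param path File path.
#' @return `read_params()` returns the restored `hpt_params`.
#' @export
write_params <- function(params, path) {
  vals <- as.list(unclass(params))
  vals <- lapply(vals, function(v) sprintf("%.17g", v))
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  vals <- yaml::read_yaml(path)
  p <- hpt_params()
  bad <- setdiff(names(vals), names(p))
  if (length(bad))
    stop("unknown parameter(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  p[names(vals)] <- as.numeric(unlist(vals))
  validate_params(p)
  structure(p, class = "hpt_params")
}

# pack the dynamic parameters (canonical order) for the compiled RHS
pack_parms <- function(params) {
  as.numeric(unclass(params)[.ode_parm_names])
}
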