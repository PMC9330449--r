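#' Patient profile
#'
#' Bundles the anthropometric characteristics that drive all personalization
#' of the thyroid-axis model: sex, height, body weight and (optionally)
#' hematocrit. Hematocrit defaults to 0.45 for male and 0.40 for female
#' patients when not supplied; BMI is derived as `weight / height^2`.
#'
#' @param sex `"male"` or `"female"` (`"m"`/`"f"` accepted, case-insensitive).
#' @param height Height in meters (warns outside 1.2--2.2 m).
#' @param weight Body weight in kg.
#' @param hematocrit Optional red-cell volume fraction in (0, 1); sex default
#'   used when `NULL`.
#'
#' @return An object of class `hpt_patient`: a list with elements `sex`,
#'   `height`, `weight`, `hematocrit` and derived `bmi`.
#' @examples
#' patient_profile("female", 1.67, 63)
#' @export
patient_profile <- function(sex, height, weight, hematocrit = NULL) {
  sex <- match_sex(sex)
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) || height <= 0)
    stop("`height` must be a single positive number (meters)", call. = FALSE)
  if (height < 1.2 || height > 2.2)
    warning("height ", height, " m is outside the supported 1.2-2.2 m range; ",
            "the anthropometric equations are extrapolated", call. = FALSE)
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) || weight <= 0)
    stop("`weight` must be a single positive number (kg)", call. = FALSE)
  if (is.null(hematocrit)) {
    hematocrit <- if (sex == "male") 0.45 else 0.40
  } else if (!is.numeric(hematocrit) || length(hematocrit) != 1L ||
             hematocrit <= 0 || hematocrit >= 1) {
    stop("`hematocrit` must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(
    list(sex = sex, height = height, weight = weight,
         hematocrit = hematocrit, bmi = weight / height^2),
    class = "hpt_patient")
}

#' @export
print.hpt_patient <- function(x, ...) {
  cat(sprintf("<hpt_patient> %s, %.2f m, %.1f kg (BMI %.1f), hematocrit %.2f\n",
              x$sex, x$height, x$weight, x$bmi, x$hematocrit))
  invisible(x)
}

match_sex <- function(sex) {
  if (inherits(sex, "hpt_patient")) return(sex$sex)
  s <- tolower(as.character(sex))
  if (s %in% c("m", "male")) return("male")
  if (s %in% c("f", "female")) return("female")
  stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
}

# fitted constants of the per-kg blood-volume curve; the exponent is < 1 so
# per-kg blood volume falls as excess weight rises
bv_constants <- function() c(a = 1.27, n_bv = 0.373)

#' Ideal body weight
#'
#' Sex-specific quadratic in height used as the anchor of the blood-volume
#' submodel ("ideal" is historical terminology from the source data, not a
#' normative target).
#'
#' @param height Height in meters.
#' @param sex `"male"` or `"female"`.
#' @return Ideal body weight in kg.
#' @examples
#' ideal_body_weight(1.76, "male")   # 77.67
#' ideal_body_weight(1.67, "female") # 62.55
#' @export
ideal_body_weight <- function(height, sex) {
  sex <- match_sex(sex)
  if (!is.numeric(height) || any(!is.finite(height)) || any(height <= 0))
    stop("`height` must be positive (meters)", call. = FALSE)
  if (any(height < 1.2) || any(height > 2.2))
    warning("height outside 1.2-2.2 m; extrapolating ideal-weight quadratic",
            call. = FALSE)
  if (sex == "male") 176.3 - 220.6 * height + 93.5 * height^2
  else               145.8 - 182.7 * height + 79.55 * height^2
}

#' Percent deviation from ideal body weight
#'
#' @param weight Body weight in kg.
#' @inheritParams ideal_body_weight
#' @return Percent deviation `100 * (weight - iBW) / iBW`.
#' @export
pct_deviation_ibw <- function(weight, height, sex) {
  if (!is.numeric(weight) || any(weight <= 0))
    stop("`weight` must be positive (kg)", call. = FALSE)
  ibw <- ideal_body_weight(height, sex)
  100 * (weight - ibw) / ibw
}

#' Blood volume from anthropometry
#'
#' Total blood volume `V_B = a * (100 + delta_iBW)^(n_bv - 1) * weight` in
#' liters, with fitted constants `a = 1.27`, `n_bv = 0.373`. Because
#' `n_bv - 1 < 0`, blood volume *per kg* decreases with excess weight.
#'
#' @inheritParams pct_deviation_ibw
#' @return Blood volume in liters.
#' @export
blood_volume <- function(weight, height, sex) {
  d <- pct_deviation_ibw(weight, height, sex)
  if (any(100 + d <= 0))
    stop("non-physical weight: deviation from ideal weight at or below -100%",
         call. = FALSE)
  k <- bv_constants()
  k[["a"]] * (100 + d)^(k[["n_bv"]] - 1) * weight
}

#' Plasma volume from anthropometry
#'
#' `V_P = V_B * (1 - hematocrit)` in liters, before rescaling to the model's
#' reference volume (see [plasma_volume_scaled()]).
#'
#' @inheritParams blood_volume
#' @param hematocrit Red-cell fraction in (0, 1); sex default when `NULL`.
#' @return Plasma volume in liters.
#' @examples
#' plasma_volume_raw(63, 1.67, "female") # ~2.66 L
#' @export
plasma_volume_raw <- function(weight, height, sex, hematocrit = NULL) {
  sex <- match_sex(sex)
  if (is.null(hematocrit)) hematocrit <- if (sex == "male") 0.45 else 0.40
  if (!is.numeric(hematocrit) || any(hematocrit <= 0) || any(hematocrit >= 1))
    stop("`hematocrit` must lie strictly between 0 and 1", call. = FALSE)
  blood_volume(weight, height, sex) * (1 - hematocrit)
}

#' Reference plasma volume
#'
#' Average of the raw plasma volumes of the reference male and female
#' patients whose heights and BMIs are model parameters (`H_Mref`, `H_Fref`,
#' `BMI_Mref`, `BMI_Fref`); reference weights follow from
#' `BW_ref = BMI_ref * H_ref^2`. This is the denominator of the plasma-volume
#' rescaling, chosen so a normal-weight patient keeps the base model's 3.2 L.
#'
#' @param params An [hpt_params()] parameter set.
#' @return Reference plasma volume in liters (about 2.77 L at defaults).
#' @export
reference_plasma_volume <- function(params = hpt_params()) {
  bw_m <- params[["BMI_Mref"]] * params[["H_Mref"]]^2
  bw_f <- params[["BMI_Fref"]] * params[["H_Fref"]]^2
  (plasma_volume_raw(bw_m, params[["H_Mref"]], "male") +
     plasma_volume_raw(bw_f, params[["H_Fref"]], "female")) / 2
}

#' Scaled (model) plasma volume
#'
#' Rescales a patient's raw plasma volume onto the base model's volume scale:
#' `V_Pnew = 3.2 * V_P(patient) / V_Pref`. By construction the mean of
#' `V_Pnew` over the two reference patients is exactly 3.2 L.
#'
#' @param patient An [patient_profile()] object.
#' @inheritParams reference_plasma_volume
#' @return Scaled plasma volume in liters.
#' @export
plasma_volume_scaled <- function(patient, params = hpt_params()) {
  stopifnot(inherits(patient, "hpt_patient"))
  vp <- plasma_volume_raw(patient$weight, patient$height, patient$sex,
                          patient$hematocrit)
  3.2 * vp / reference_plasma_volume(params)
}

#' TSH distribution volume
#'
#' TSH distributes over plasma plus a fixed 2.0 L of non-vascular tissue:
#' `V_TSHnew = 5.2 + (V_Pnew - 3.2)`.
#'
#' @param v_p_new Scaled plasma volume in liters.
#' @return TSH distribution volume in liters (> 2).
#' @export
tsh_distribution_volume <- function(v_p_new) {
  if (any(v_p_new <= 0)) stop("`v_p_new` must be positive", call. = FALSE)
  out <- 5.2 + (v_p_new - 3.2)
  if (any(out <= 0)) stop("non-physical TSH distribution volume <= 0", call. = FALSE)
  out
}

#' Allometrically scaled T3 clearance
#'
#' The fast-pool fractional T3 clearance rate `k05` scales with body weight as
#' `(BW / BW_ref)^0.75`, relative to the sex-specific reference weight; the
#' male branch carries the additional factor `C_M`.
#'
#' @inheritParams plasma_volume_scaled
#' @return Scaled `k05` in 1/h.
#' @export
t3_clearance_scaled <- function(patient, params = hpt_params()) {
  stopifnot(inherits(patient, "hpt_patient"))
  k05 <- params[["k05"]]
  if (patient$sex == "male") {
    bw_ref <- params[["BMI_Mref"]] * params[["H_Mref"]]^2
    params[["C_M"]] * k05 * (patient$weight / bw_ref)^0.75
  } else {
    bw_ref <- params[["BMI_Fref"]] * params[["H_Fref"]]^2
    k05 * (patient$weight / bw_ref)^0.75
  }
}

#' Read a patient table
#'
#' Reads a CSV with columns `sex` (m/f, case-insensitive), `height_m`,
#' `weight_kg` and optional `hematocrit`, returning a list of
#' [patient_profile()] objects.
#'
#' @param path Path to the CSV file.
#' @return List of `hpt_patient` objects; names taken from an `id` column when
#'   present.
#' @export
read_patients <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sex", "height_m", "weight_kg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("patient table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    hem <- if ("hematocrit" %in% names(df) && is.finite(df$hematocrit[i]))
      df$hematocrit[i] else NULL
    tryCatch(
      patient_profile(df$sex[i], df$height_m[i], df$weight_kg[i], hem),
      error = function(e) stop("patient table ", path, " line ", i + 1L, ": ",
                               conditionMessage(e), call. = FALSE))
  })
  names(out) <- if ("id" %in% names(df)) as.character(df$id) else NULL
  out
}
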