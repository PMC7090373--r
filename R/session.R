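#' Construct a rebreathing session
#'
#' An `ocor_session` holds everything measured in one CO-rebreathing test:
#' the administered CO volume, when the subject disconnected from the
#' rebreathing circuit, and the baseline and timed venous COHb% readings.
#' Replicate hemoximeter readings share a `time_min`; baseline draws use the
#' convention `time_min = -1` (the draw precedes CO inhalation and its exact
#' time does not enter any calculation).
#'
#' @param subject_id identifier (coerced to character).
#' @param dose_co_ml administered CO volume, ml at syringe conditions; > 0.
#' @param samples data.frame with columns `time_min` (minutes from the start
#'   of CO inhalation; negative = baseline) and `cohb_pct` (COHb, percent of
#'   total Hb, each in \[0, 100\]). One row per replicate reading.
#' @param rebreathe_end_min minutes at which the subject disconnects from the
#'   rebreathing circuit (CO exhalation to room air starts here); default 2.
#' @param residual_system_co_ml CO left in spirometer + lung at disconnection,
#'   ml (optional; `NA` treated as 0 in calculations).
#' @param exhale_rate_ml_per_min measured per-subject CO exhalation rate after
#'   disconnection, ml/min (optional; when absent the calculator falls back to
#'   the rate in [correction_params()]).
#' @param weight_kg,dose_ml_per_kg subject mass and weight-indexed dose, used
#'   only by QC dose-range checks (optional; `dose_ml_per_kg` is derived from
#'   `dose_co_ml / weight_kg` when omitted and weight is known).
#' @param ambient_temp_c,ambient_pressure_mmhg ambient conditions for optional
#'   STPD gas-volume standardization.
#' @return object of class `ocor_session`.
#' @examples
#' s <- ocor_session("p1", dose_co_ml = 50,
#'   samples = data.frame(time_min = c(-1, -1, 6, 6, 8, 8),
#'                        cohb_pct = c(1.6, 1.7, 6.6, 6.7, 6.7, 6.6)))
#' seven_min_cohb(s)
#' @export
ocor_session <- function(subject_id, dose_co_ml, samples,
                         rebreathe_end_min = 2,
                         residual_system_co_ml = NA_real_,
                         exhale_rate_ml_per_min = NA_real_,
                         weight_kg = NA_real_,
                         dose_ml_per_kg = NA_real_,
                         ambient_temp_c = NA_real_,
                         ambient_pressure_mmhg = NA_real_) {
  if (!is.data.frame(samples) || !all(c("time_min", "cohb_pct") %in% names(samples)))
    ocor_abort("ocor_config_error",
               "`samples` must be a data.frame with columns time_min and cohb_pct")
  if (!is.numeric(dose_co_ml) || length(dose_co_ml) != 1L || is.na(dose_co_ml) ||
      dose_co_ml <= 0)
    ocor_abort("ocor_domain_error", "dose_co_ml must be a single positive number")
  if (!is.numeric(rebreathe_end_min) || rebreathe_end_min <= 0)
    ocor_abort("ocor_domain_error", "rebreathe_end_min must be positive")
  bad <- which(!is.finite(samples$cohb_pct) | samples$cohb_pct < 0 |
                 samples$cohb_pct > 100)
  if (length(bad))
    ocor_abort("ocor_domain_error",
               sprintf("cohb_pct outside [0, 100] in sample row(s) %s",
                       paste(bad, collapse = ", ")))
  if (!any(samples$time_min < 0))
    ocor_abort("ocor_missing_data", "session has no baseline sample (time_min < 0)")
  timed <- sort(unique(samples$time_min[samples$time_min >= 0]))
  if (anyDuplicated(timed))
    ocor_abort("ocor_config_error", "timed samples must be strictly increasing")
  if (is.na(dose_ml_per_kg) && !is.na(weight_kg) && weight_kg > 0)
    dose_ml_per_kg <- dose_co_ml / weight_kg
  structure(list(
    subject_id = as.character(subject_id),
    dose_co_ml = as.numeric(dose_co_ml),
    rebreathe_end_min = as.numeric(rebreathe_end_min),
    residual_system_co_ml = as.numeric(residual_system_co_ml),
    exhale_rate_ml_per_min = as.numeric(exhale_rate_ml_per_min),
    weight_kg = as.numeric(weight_kg),
    dose_ml_per_kg = as.numeric(dose_ml_per_kg),
    ambient_temp_c = as.numeric(ambient_temp_c),
    ambient_pressure_mmhg = as.numeric(ambient_pressure_mmhg),
    samples = samples[order(samples$time_min), c("time_min", "cohb_pct"),
                      drop = FALSE]
  ), class = "ocor_session")
}

#' @export
print.ocor_session <- function(x, ...) {
  nt <- length(unique(x$samples$time_min[x$samples$time_min >= 0]))
  cat(sprintf("<ocor_session %s: %.0f ml CO, %d baseline reading(s), %d timed sample(s)>\n",
              x$subject_id, x$dose_co_ml, sum(x$samples$time_min < 0), nt))
  invisible(x)
}

#' Physical constants and loss-model parameters
#'
#' Bundles every constant entering the tHb-mass calculation so each is named
#' and overridable.
#'
#' @param huefner_ml_per_g CO binding capacity of haemoglobin (Huefner
#'   constant), ml CO per g Hb. Default 1.39.
#' @param k_myo_per_min fraction of the administered dose diffusing to
#'   myoglobin per minute. Default 0.00175, so a 40–72 ml dose loses
#'   1.4–2.5 ml by 20 min.
#' @param exhale_rate_ml_per_min default CO exhalation rate after circuit
#'   disconnection, ml/min, used when the session has no measured rate.
#'   Default 0.15 (2.7 ml over 18 min).
#' @param apply_stpd standardize the administered volume to STPD using the
#'   session's ambient temperature and pressure. Default `FALSE` (syringe
#'   volumes used as recorded).
#' @param p_h2o_table saturated water-vapour pressure table (mmHg) used by
#'   the STPD correction; named numeric vector keyed by temperature in
#'   degrees Celsius, linearly interpolated.
#' @return list of class `correction_params`.
#' @export
correction_params <- function(huefner_ml_per_g = 1.39,
                              k_myo_per_min = 0.00175,
                              exhale_rate_ml_per_min = 0.15,
                              apply_stpd = FALSE,
                              p_h2o_table = saturated_vapor_pressure_mmhg) {
  if (huefner_ml_per_g <= 0)
    ocor_abort("ocor_domain_error", "huefner_ml_per_g must be > 0")
  if (k_myo_per_min < 0 || exhale_rate_ml_per_min < 0)
    ocor_abort("ocor_domain_error", "loss rates must be non-negative")
  structure(list(
    huefner_ml_per_g = huefner_ml_per_g,
    k_myo_per_min = k_myo_per_min,
    exhale_rate_ml_per_min = exhale_rate_ml_per_min,
    apply_stpd = apply_stpd,
    p_h2o_table = p_h2o_table
  ), class = "correction_params")
}

#' Saturated water-vapour pressure (mmHg) at selected temperatures (deg C)
#'
#' Standard physiology-laboratory table used for STPD gas-volume
#' standardization; values between tabulated temperatures are interpolated
#' linearly.
#' @format named numeric vector; names are temperatures in degrees Celsius.
#' @export
saturated_vapor_pressure_mmhg <- c(
  "0" = 4.6, "5" = 6.5, "10" = 9.2, "15" = 12.8, "20" = 17.5,
  "25" = 23.8, "30" = 31.8, "35" = 42.2, "37" = 47.1, "40" = 55.3
)
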