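#' Baseline COHb of a session
#'
#' Mean over all baseline replicate readings (every reading with
#' `time_min < 0`). Baseline draws precede CO inhalation; replicates are
#' pooled because hemoximeters quantize to one decimal and averaging is the
#' standard mitigation.
#'
#' @param session an [ocor_session()].
#' @return baseline COHb, percent.
#' @export
baseline_cohb <- function(session) {
  r <- session$samples$cohb_pct[session$samples$time_min < 0]
  if (!length(r))
    ocor_abort("ocor_missing_data", "session has no baseline sample")
  mean(r)
}

# unique timed sample times of a session (time_min >= 0)
session_times <- function(session) {
  sort(unique(session$samples$time_min[session$samples$time_min >= 0]))
}

#' COHb at a nominal sampling time
#'
#' Looks up the timed sample nearest `time_min` within a +/- 0.5 min
#' tolerance (ties broken toward the earlier sample) and returns the mean of
#' its replicate readings.
#'
#' @inheritParams baseline_cohb
#' @param time_min nominal sampling time, minutes from the start of CO
#'   inhalation.
#' @param tolerance_min lookup half-window, minutes. Default 0.5.
#' @return COHb, percent.
#' @export
cohb_at <- function(session, time_min, tolerance_min = 0.5) {
  tt <- session_times(session)
  d <- abs(tt - time_min)
  ok <- which(d <= tolerance_min + 1e-12)
  if (!length(ok))
    ocor_abort("ocor_missing_timepoint",
               sprintf("no sample within %.2f min of t = %g in session %s",
                       tolerance_min, time_min, session$subject_id))
  # nearest; on a tie take the earlier sample
  hit <- ok[order(d[ok], tt[ok])][1L]
  keep <- session$samples$time_min == tt[hit]
  mean(session$samples$cohb_pct[keep])
}

#' The "7-min value": mean of the 6- and 8-min COHb readings
#'
#' The canonical oCOR measurement point: circulatory mixing of the CO bolus
#' is complete by 6–8 min in health, so the 6- and 8-min venous COHb values
#' are averaged.
#'
#' @inheritParams baseline_cohb
#' @return COHb, percent.
#' @export
seven_min_cohb <- function(session) {
  (cohb_at(session, 6) + cohb_at(session, 8)) / 2
}

#' Rise in COHb from baseline
#'
#' @inheritParams cohb_at
#' @param time_min sampling time in minutes; the special value 7 denotes the
#'   symbolic "7-min value" (mean of 6 and 8 min).
#' @return delta COHb, percent; may be negative (callers flag or reject).
#' @export
delta_cohb <- function(session, time_min) {
  post <- if (identical(as.numeric(time_min), 7)) seven_min_cohb(session)
          else cohb_at(session, time_min)
  post - baseline_cohb(session)
}

#' CO lost to myoglobin by a given time
#'
#' Modeled as linear in time and proportional to the administered dose:
#' `k_myo_per_min * dose_co_ml * time_min`. At the default rate a 40–72 ml
#' dose loses 1.4–2.5 ml over 20 min.
#'
#' @param dose_co_ml administered CO volume, ml.
#' @param time_min minutes since the start of CO inhalation; >= 0.
#' @param params a [correction_params()].
#' @return ml of CO.
#' @export
co_loss_myoglobin <- function(dose_co_ml, time_min, params = correction_params()) {
  if (any(time_min < 0))
    ocor_abort("ocor_domain_error", "time_min must be non-negative")
  params$k_myo_per_min * dose_co_ml * time_min
}

#' CO exhaled to room air by a given time
#'
#' Zero while the subject is on the closed rebreathing circuit; afterwards a
#' constant per-minute rate. The session's measured exhalation rate is used
#' when present, otherwise the default in `params`.
#'
#' @inheritParams cohb_at
#' @param params a [correction_params()].
#' @return ml of CO.
#' @export
co_loss_exhaled <- function(session, time_min, params = correction_params()) {
  if (any(time_min < 0))
    ocor_abort("ocor_domain_error", "time_min must be non-negative")
  rate <- session$exhale_rate_ml_per_min
  if (is.na(rate)) rate <- params$exhale_rate_ml_per_min
  rate * pmax(0, time_min - session$rebreathe_end_min)
}

#' Standardize a gas volume to STPD
#'
#' `V * (P - P_H2O(T)) / 760 * 273.15 / (273.15 + T)`, with the saturated
#' water-vapour pressure interpolated from `params$p_h2o_table`. Identity
#' when `params$apply_stpd` is `FALSE`.
#'
#' @param volume_ml gas volume, ml.
#' @param temp_c ambient temperature, deg C.
#' @param pressure_mmhg ambient barometric pressure, mmHg.
#' @param params a [correction_params()].
#' @return ml at STPD (or the input unchanged when the correction is off).
#' @export
stpd <- function(volume_ml, temp_c = NA_real_, pressure_mmhg = NA_real_,
                 params = correction_params()) {
  if (!isTRUE(params$apply_stpd)) return(volume_ml)
  if (is.na(temp_c) || is.na(pressure_mmhg))
    ocor_abort("ocor_config_error",
               "STPD correction requires ambient temperature and pressure")
  tab <- params$p_h2o_table
  tk <- as.numeric(names(tab))
  if (temp_c < min(tk) || temp_c > max(tk))
    ocor_abort("ocor_domain_error",
               sprintf("temperature %g outside the vapour-pressure table (%g-%g)",
                       temp_c, min(tk), max(tk)))
  p_h2o <- stats::approx(tk, tab, xout = temp_c)$y
  volume_ml * (pressure_mmhg - p_h2o) / 760 * 273.15 / (273.15 + temp_c)
}

#' CO bound to circulating haemoglobin at a given time
#'
#' The administered dose (STPD-standardized when configured), minus CO left
#' in the spirometer and lung at disconnection, minus CO exhaled since
#' disconnection, minus CO diffused to myoglobin.
#'
#' @inheritParams co_loss_exhaled
#' @return ml of CO; errors if losses meet or exceed the dose.
#' @export
absorbed_co <- function(session, time_min, params = correction_params()) {
  dose <- stpd(session$dose_co_ml, session$ambient_temp_c,
               session$ambient_pressure_mmhg, params)
  residual <- session$residual_system_co_ml
  if (is.na(residual)) residual <- 0
  m <- dose - residual - co_loss_exhaled(session, time_min, params) -
    co_loss_myoglobin(session$dose_co_ml, time_min, params)
  if (any(m <= 0))
    ocor_abort("ocor_infeasible_session",
               sprintf("CO losses exceed administered dose in session %s",
                       session$subject_id))
  m
}

#' Total haemoglobin mass from a timed COHb sample
#'
#' The core oCOR dilution relation: the CO bound to circulating Hb at time t
#' raised COHb by delta COHb percentage points, and each gram of Hb binds
#' `huefner_ml_per_g` ml of CO, so
#'
#'   tHb-mass (g) = M_CO(t) * 100 / (delta COHb(t) * huefner_ml_per_g)
#'
#' `time_min = 7` uses the "7-min value" (mean of the 6- and 8-min readings)
#' with losses evaluated at t = 7.
#'
#' @inheritParams co_loss_exhaled
#' @return one-row data.frame: `time_min`, `delta_cohb_pct`, `absorbed_co_ml`,
#'   `thb_mass_g`, `flags` (comma-separated QC annotations, "" if none).
#' @export
thb_mass_at <- function(session, time_min, params = correction_params()) {
  d <- delta_cohb(session, time_min)
  if (d <= 0)
    ocor_abort("ocor_invalid_rise",
               sprintf("delta COHb = %.3f%% at t = %g in session %s (must be > 0)",
                       d, time_min, session$subject_id))
  m_co <- absorbed_co(session, time_min, params)
  flags <- character()
  if (d < 4) flags <- c(flags, "INSUFFICIENT_RISE")
  data.frame(
    time_min = as.numeric(time_min),
    delta_cohb_pct = d,
    absorbed_co_ml = m_co,
    thb_mass_g = m_co * 100 / (d * params$huefner_ml_per_g),
    flags = paste(flags, collapse = ","),
    stringsAsFactors = FALSE
  )
}
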