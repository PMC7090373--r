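#' QC policy thresholds
#'
#' @param min_delta_pct minimum acceptable COHb rise at the 7-min value,
#'   percentage points; smaller rises make the tHb-mass estimate unreliable
#'   (hemoximeter quantization dominates). Default 4.0; below it a session is
#'   invalid.
#' @param target_delta_max_pct top of the desired rise band; above it the
#'   session is flagged (precision/safety tradeoff) but remains valid.
#'   Default 6.5.
#' @param peak_max_pct peak COHb level above which a warning is raised (the
#'   session remains valid; studies have retained peaks just over 10%).
#'   Default 10.0.
#' @param dose_range_ml_per_kg acceptable weight-indexed dose range.
#'   Default c(0.4, 1.0).
#' @return list of class `qc_policy`.
#' @export
qc_policy <- function(min_delta_pct = 4.0,
                      target_delta_max_pct = 6.5,
                      peak_max_pct = 10.0,
                      dose_range_ml_per_kg = c(0.4, 1.0)) {
  structure(list(
    min_delta_pct = min_delta_pct,
    target_delta_max_pct = target_delta_max_pct,
    peak_max_pct = peak_max_pct,
    dose_range_ml_per_kg = dose_range_ml_per_kg
  ), class = "qc_policy")
}

#' Validate one session against the oCOR acceptability rules
#'
#' Flags raised:
#' \describe{
#'   \item{INSUFFICIENT_RISE}{7-min delta COHb below `min_delta_pct`
#'     (invalidating).}
#'   \item{NEGATIVE_DELTA}{7-min delta COHb at or below zero (invalidating).}
#'   \item{DELTA_ABOVE_TARGET_BAND}{7-min delta COHb above
#'     `target_delta_max_pct` (warning only).}
#'   \item{PEAK_HIGH}{any timed COHb reading at or above `peak_max_pct`
#'     (warning only).}
#'   \item{DOSE_OUT_OF_RANGE}{weight-indexed dose outside
#'     `dose_range_ml_per_kg` (warning only; checked only when the session
#'     knows its ml/kg dose).}
#'   \item{MISSING_TIMEPOINT}{6- or 8-min sample absent, so the 7-min value
#'     cannot be formed (invalidating).}
#' }
#' A session is valid iff none of the invalidating flags is raised.
#'
#' @param session an [ocor_session()].
#' @param params a [correction_params()] (reserved for threshold variants
#'   that depend on corrected quantities; the rise itself is correction-free).
#' @param policy a [qc_policy()].
#' @return one-row data.frame: `session_id`, `valid`, `flags`
#'   (comma-separated), `delta7_pct`, `peak_cohb_pct`, `dose_ml_per_kg`.
#' @export
validate_session <- function(session, params = correction_params(),
                             policy = qc_policy()) {
  flags <- character()
  delta7 <- NA_real_
  peak <- {
    timed <- session$samples$cohb_pct[session$samples$time_min >= 0]
    if (length(timed)) max(timed) else NA_real_
  }
  d7 <- tryCatch(delta_cohb(session, 7), ocor_missing_timepoint = function(e) NULL,
                 ocor_missing_data = function(e) NULL)
  if (is.null(d7)) {
    flags <- c(flags, "MISSING_TIMEPOINT")
  } else {
    delta7 <- d7
    # strict thresholds with a guard against float round-off: a rise of
    # exactly 4.0 is acceptable even when computed as 3.999999...
    if (d7 <= 0) flags <- c(flags, "NEGATIVE_DELTA")
    else if (d7 < policy$min_delta_pct - 1e-9) flags <- c(flags, "INSUFFICIENT_RISE")
    if (d7 > policy$target_delta_max_pct + 1e-9)
      flags <- c(flags, "DELTA_ABOVE_TARGET_BAND")
  }
  if (!is.na(peak) && peak >= policy$peak_max_pct)
    flags <- c(flags, "PEAK_HIGH")
  mlkg <- session$dose_ml_per_kg
  if (!is.na(mlkg) &&
      (mlkg < policy$dose_range_ml_per_kg[1] || mlkg > policy$dose_range_ml_per_kg[2]))
    flags <- c(flags, "DOSE_OUT_OF_RANGE")
  valid <- !any(flags %in% c("INSUFFICIENT_RISE", "NEGATIVE_DELTA",
                             "MISSING_TIMEPOINT"))
  data.frame(session_id = session$subject_id, valid = valid,
             flags = paste(flags, collapse = ","),
             delta7_pct = delta7, peak_cohb_pct = peak,
             dose_ml_per_kg = mlkg, stringsAsFactors = FALSE)
}

#' Partition a cohort of sessions by QC validity
#'
#' @param sessions list of [ocor_session()] objects.
#' @param params a [correction_params()].
#' @param policy a [qc_policy()].
#' @return list with `valid` and `excluded` (order-preserving sublists of
#'   `sessions`) and `report` (row-bound [validate_session()] output).
#' @export
filter_cohort <- function(sessions, params = correction_params(),
                          policy = qc_policy()) {
  if (!length(sessions))
    return(list(valid = list(), excluded = list(),
                report = validate_session_empty()))
  report <- do.call(rbind, lapply(sessions, validate_session,
                                  params = params, policy = policy))
  list(valid = sessions[report$valid],
       excluded = sessions[!report$valid],
       report = report)
}

validate_session_empty <- function() {
  data.frame(session_id = character(), valid = logical(), flags = character(),
             delta7_pct = numeric(), peak_cohb_pct = numeric(),
             dose_ml_per_kg = numeric(), stringsAsFactors = FALSE)
}
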