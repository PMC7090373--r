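#' Packaged study fixture: per-patient published values
#'
#' Transcribed per-patient values from a published pilot study of CO
#' rebreathing in chronic liver disease: the 13 analysed patients (venous
#' \[Hb\], tHb-mass, administered CO dose in ml and ml/kg, and the 7-min COHb
#' rise), the 3 patients excluded for an insufficient rise, and the printed
#' per-timepoint group summaries of COHb% (median, IQR) and tHb-mass
#' (mean, SD).
#'
#' `table1` also carries the per-patient dosing annotations needed to replay
#' the dose decisions: `performance_status`, `polycythemia`,
#' `anemia_reduction` (`NA` = follow policy, `FALSE` = reduction waived,
#' `TRUE` = reduction forced) and `extra_steps` (signed discretionary 0.1
#' ml/kg steps). Patient weights are not published; `weight_kg` is the value
#' implied by dose_ml / dose_ml_per_kg (synthetic reconstruction, flagged by
#' `weight_implied = TRUE`).
#'
#' @param verify check the transcription against its stored checksum and fail
#'   loudly on any edit. Default TRUE.
#' @return list of class `study_fixture` with `table1`, `table2`,
#'   `timepoint_means` data.frames.
#' @export
study_fixture <- function(verify = TRUE) {
  table1 <- data.frame(
    id = sprintf("t1_p%02d", 1:13),
    sex = c("female", "male", "male", "male", "female", "male", "male",
            "male", "male", "male", "male", "male", "male"),
    hb_g_l = c(98, 104, 105, 117, 113, 93, 132, 101, 144, 184, 100, 118, 121),
    thb_mass_g = c(396, 628, 431, 664, 581, 662, 590, 518, 883, 799, 648, 787, 828),
    dose_co_ml = c(50, 48, 44, 64, 40, 64, 52, 46, 60, 64, 72, 70, 70),
    dose_ml_per_kg = c(0.6, 0.5, 0.6, 0.8, 0.7, 0.7, 0.8, 0.6, 0.7, 1.0, 0.8, 0.9, 0.8),
    delta_cohb7_pct = c(7.2, 4.5, 5.5, 5.8, 4.0, 5.9, 4.5, 5.0, 4.2, 4.9, 6.7, 5.5, 4.7),
    performance_status = c(1L, 2L, 2L, 1L, 1L, 1L, 1L, 2L, 1L, 0L, 1L, 0L, 1L),
    polycythemia = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     FALSE, TRUE, FALSE, FALSE, FALSE),
    anemia_reduction = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, NA, TRUE,
                         TRUE, NA, FALSE, FALSE, FALSE),
    extra_steps = c(0L, -1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    weight_implied = TRUE,
    stringsAsFactors = FALSE
  )
  table1$weight_kg <- table1$dose_co_ml / table1$dose_ml_per_kg

  table2 <- data.frame(
    id = sprintf("t2_p%02d", 1:3),
    age_y = c(49, 50, 50),
    sex = c("male", "female", "female"),
    height_cm = c(176, 162, 165.5),
    weight_kg = c(65.7, 57.8, 66.3),
    bmi = c(21.2, 22.0, 24.2),
    hb_g_l = c(105, 128, 129),
    dose_co_ml = c(46, 36, 40),
    delta_cohb7_pct = c(3.2, 2.6, 2.3),
    stringsAsFactors = FALSE
  )

  timepoint_means <- data.frame(
    time_min = c(6, 7, 8, 10, 12, 15, 20),
    thb_mean_g = c(647.3, 647.3, 648.6, 653.4, 659.7, 653.5, 651.4),
    thb_sd_g = c(149.1, 148.9, 149.1, 162.0, 163.2, 164.9, 167.9),
    cohb_median = c(6.33, 6.30, 6.30, 6.33, 6.33, 6.37, 6.27),
    cohb_q1 = c(6.25, 6.21, 6.20, 6.00, 5.90, 5.80, 5.70),
    cohb_q3 = c(7.46, 7.47, 7.47, 7.50, 7.40, 7.33, 7.20)
  )

  fx <- structure(list(table1 = table1, table2 = table2,
                       timepoint_means = timepoint_means),
                  class = "study_fixture")
  if (verify && !identical(fixture_checksum(fx), .fixture_checksum))
    ocor_abort("ocor_config_error",
               "study fixture failed its checksum: the transcription was edited")
  fx
}

# FNV-1a (32-bit) over a canonical serialization; no external digest
# dependency needed for a tamper check of this size
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte since b < 256
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    # h * 16777619 mod 2^32; 16777619 = 2^24 + 403 and
    # (h * 2^24) mod 2^32 = (h mod 2^8) * 2^24, all exact in doubles
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  # format as 8 hex digits; h may exceed .Machine$integer.max so split it
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Checksum of a study fixture
#' @param fixture a [study_fixture()] (any list of data.frames).
#' @return 8-hex-digit string.
#' @export
fixture_checksum <- function(fixture) {
  canon <- paste(vapply(unclass(fixture), function(df) {
    paste(vapply(df, function(col) paste(format(col, digits = 12), collapse = ","),
                 character(1)), collapse = ";")
  }, character(1)), collapse = "|")
  fnv1a32(canon)
}

.fixture_checksum <- "a1e17c65"

#' Reconstruct sessions from the study fixture
#'
#' Builds minimal synthetic [ocor_session()] objects that carry each
#' patient's published dose and 7-min COHb rise: a baseline reading at a
#' nominal 1.6% and 6-/8-min readings at baseline + published rise. Only the
#' quantities the publication printed are faithful; wash-in shape and absolute
#' COHb levels are reconstructions (per-patient curves were published only as
#' figures).
#'
#' @param fixture a [study_fixture()].
#' @param baseline_pct nominal baseline COHb used in the reconstruction.
#'   Default 1.6.
#' @return list of 16 sessions (13 analysed + 3 excluded).
#' @export
sessions_from_fixture <- function(fixture = study_fixture(), baseline_pct = 1.6) {
  build <- function(id, dose, mlkg, weight, delta) {
    ocor_session(id, dose_co_ml = dose,
                 samples = data.frame(
                   time_min = c(-1, 6, 8),
                   cohb_pct = baseline_pct + c(0, delta, delta)),
                 weight_kg = weight, dose_ml_per_kg = mlkg)
  }
  t1 <- fixture$table1
  t2 <- fixture$table2
  c(
    lapply(seq_len(nrow(t1)), function(i)
      build(t1$id[i], t1$dose_co_ml[i], t1$dose_ml_per_kg[i],
            t1$weight_kg[i], t1$delta_cohb7_pct[i])),
    lapply(seq_len(nrow(t2)), function(i)
      build(t2$id[i], t2$dose_co_ml[i], t2$dose_co_ml[i] / t2$weight_kg[i],
            t2$weight_kg[i], t2$delta_cohb7_pct[i]))
  )
}

#' Replay the dosing decisions of the analysed patients
#'
#' Runs [recommend_dose()] for every analysed patient using the fixture's
#' per-patient annotations and compares against the published ml/kg dose.
#'
#' @param fixture a [study_fixture()].
#' @param policy a [dosing_policy()].
#' @return data.frame: `id`, `published_ml_per_kg`, `recommended_ml_per_kg`,
#'   `match`.
#' @export
reproduce_dosing <- function(fixture = study_fixture(), policy = dosing_policy()) {
  t1 <- fixture$table1
  rec <- vapply(seq_len(nrow(t1)), function(i) {
    subj <- ocor_subject(t1$id[i], t1$sex[i],
                         weight_kg = t1$weight_kg[i], height_cm = 175,
                         hb_g_l = t1$hb_g_l[i],
                         performance_status = t1$performance_status[i],
                         training_status = "debilitated",
                         polycythemia = t1$polycythemia[i])
    recommend_dose(subj, policy,
                   apply_anemia_reduction = t1$anemia_reduction[i],
                   extra_steps = t1$extra_steps[i])$ml_per_kg
  }, numeric(1))
  data.frame(id = t1$id, published_ml_per_kg = t1$dose_ml_per_kg,
             recommended_ml_per_kg = rec,
             match = abs(rec - t1$dose_ml_per_kg) < 1e-9,
             stringsAsFactors = FALSE)
}
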