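#' Read rebreathing sessions from a long-format CSV or JSON table
#'
#' Expected columns (one row per replicate hemoximeter reading):
#' `subject_id`, `dose_co_ml`, `sample_time_min` (minutes from the start of
#' CO inhalation; -1 = baseline draw), `cohb_pct`. Optional per-subject
#' columns: `sex`, `age_y`, `height_cm`, `weight_kg`, `hb_g_l`, `hb_unit`
#' ("g/l" default; "g/dl" values are multiplied by 10 on read), `hct`,
#' `performance_status`, `rebreathe_end_min`, `residual_system_co_ml`,
#' `exhale_rate_ml_per_min`, `dose_ml_per_kg`, `replicate_index`.
#' Schema violations are reported with the offending row number.
#'
#' @param path CSV (".csv") or JSON (".json") file.
#' @return list: `sessions` (list of [ocor_session()]) and `subjects`
#'   (data.frame of per-subject covariates, one row per subject).
#' @export
read_sessions <- function(path) {
  if (!file.exists(path))
    ocor_abort("ocor_io_error", sprintf("file not found: %s", path))
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  sessions_from_table(tab)
}

#' Build sessions from an in-memory long-format table
#'
#' @param tab data.frame in the [read_sessions()] schema.
#' @return same structure as [read_sessions()].
#' @export
sessions_from_table <- function(tab) {
  required <- c("subject_id", "dose_co_ml", "sample_time_min", "cohb_pct")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    ocor_abort("ocor_io_error",
               sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  bad <- which(!is.finite(tab$cohb_pct) | tab$cohb_pct < 0 | tab$cohb_pct > 100)
  if (length(bad))
    ocor_abort("ocor_io_error",
               sprintf("cohb_pct outside [0, 100] at row(s) %s, column cohb_pct",
                       paste(bad, collapse = ", ")))
  if (!"replicate_index" %in% names(tab)) {
    tab$replicate_index <- stats::ave(seq_len(nrow(tab)),
                                      tab$subject_id, tab$sample_time_min,
                                      FUN = seq_along)
  }
  key <- paste(tab$subject_id, tab$sample_time_min, tab$replicate_index)
  if (anyDuplicated(key))
    ocor_abort("ocor_io_error",
               sprintf("duplicate (subject_id, sample_time_min, replicate_index) at row(s) %s",
                       paste(which(duplicated(key)), collapse = ", ")))
  if ("hb_g_l" %in% names(tab) && "hb_unit" %in% names(tab)) {
    dl <- !is.na(tab$hb_unit) & tab$hb_unit == "g/dl"
    tab$hb_g_l[dl] <- tab$hb_g_l[dl] * 10
    tab$hb_unit[dl] <- "g/l"
  }
  opt <- function(sub, col, default = NA_real_)
    if (col %in% names(sub)) sub[[col]][1] else default

  ids <- unique(tab$subject_id)
  sessions <- lapply(ids, function(id) {
    sub <- tab[tab$subject_id == id, ]
    ocor_session(id, dose_co_ml = sub$dose_co_ml[1],
                 samples = data.frame(time_min = sub$sample_time_min,
                                      cohb_pct = sub$cohb_pct),
                 rebreathe_end_min = opt(sub, "rebreathe_end_min", 2),
                 residual_system_co_ml = opt(sub, "residual_system_co_ml"),
                 exhale_rate_ml_per_min = opt(sub, "exhale_rate_ml_per_min"),
                 weight_kg = opt(sub, "weight_kg"),
                 dose_ml_per_kg = opt(sub, "dose_ml_per_kg"),
                 ambient_temp_c = opt(sub, "ambient_temp_c"),
                 ambient_pressure_mmhg = opt(sub, "ambient_pressure_mmhg"))
  })
  cov_cols <- intersect(c("subject_id", "sex", "age_y", "height_cm", "weight_kg",
                          "hb_g_l", "hct", "performance_status"), names(tab))
  subjects <- unique(tab[, cov_cols, drop = FALSE])
  list(sessions = sessions, subjects = subjects)
}

#' Write sessions to a long-format CSV (or JSON)
#'
#' Inverse of [read_sessions()]: `read_sessions(write_sessions(s, f))` is the
#' identity on every stored field.
#'
#' @param sessions list of [ocor_session()] objects.
#' @param path output path; format chosen by extension (.csv or .json).
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  rows <- lapply(sessions, function(s) {
    n <- nrow(s$samples)
    data.frame(subject_id = s$subject_id,
               dose_co_ml = s$dose_co_ml,
               rebreathe_end_min = s$rebreathe_end_min,
               residual_system_co_ml = s$residual_system_co_ml,
               exhale_rate_ml_per_min = s$exhale_rate_ml_per_min,
               weight_kg = s$weight_kg,
               dose_ml_per_kg = s$dose_ml_per_kg,
               sample_time_min = s$samples$time_min,
               cohb_pct = s$samples$cohb_pct,
               replicate_index = stats::ave(seq_len(n), s$samples$time_min,
                                            FUN = seq_along),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

# small stable hash of an R object for provenance blocks
config_hash <- function(x) {
  fnv1a32(paste(deparse(x), collapse = "\n"))
}

#' Run the full analysis pipeline over a set of sessions
#'
#' QC gating, per-time tHb-mass for every valid session, per-timepoint cohort
#' summaries, the 7-vs-20-min paired contrast, the repeated-measures ANOVA
#' across the measured grid, and (when \[Hb\] and hematocrit are supplied)
#' blood/red-cell/plasma-volume derivatives at the 7-min tHb-mass.
#'
#' @param sessions list of [ocor_session()] objects.
#' @param subjects optional data.frame with `subject_id`, `hb_g_l` and
#'   (optionally) `hct` for volume derivatives.
#' @param params a [correction_params()].
#' @param policy a [qc_policy()].
#' @param times timecourse grid (7 = symbolic 7-min value).
#' @param anova_times grid for the repeated-measures ANOVA (measured times
#'   only).
#' @return list of class `ocor_results`: `qc`, `timecourse`, `summary`,
#'   `contrast`, `anova`, `volumes`, `provenance`.
#' @export
run_pipeline <- function(sessions, subjects = NULL,
                         params = correction_params(),
                         policy = qc_policy(),
                         times = c(6, 7, 8, 10, 12, 15, 20),
                         anova_times = c(6, 8, 10, 12, 15, 20)) {
  if (!length(sessions))
    ocor_abort("ocor_config_error", "no sessions supplied")
  qc <- filter_cohort(sessions, params, policy)
  if (!length(qc$valid))
    ocor_abort("ocor_config_error", "no valid sessions after QC")
  tc <- cohort_timecourse(qc$valid, times = times, params = params)
  summ <- if (length(qc$valid) >= 2) timepoint_summary(tc, times) else NULL
  contrast <- if (length(qc$valid) >= 2) paired_contrast(tc, 7, 20) else NULL
  anova <- if (length(qc$valid) >= 2)
    repeated_measures_anova(tc, anova_times) else NULL
  volumes <- NULL
  if (!is.null(subjects) && all(c("subject_id", "hb_g_l") %in% names(subjects))) {
    t7 <- tc[tc$time_min == 7 & !is.na(tc$thb_mass_g), ]
    m <- merge(t7[, c("subject_id", "thb_mass_g")], subjects, by = "subject_id")
    if (nrow(m)) {
      hct <- if ("hct" %in% names(m)) m$hct else NA_real_
      vols <- lapply(seq_len(nrow(m)), function(i) {
        if (is.na(hct[i]))
          return(data.frame(bv_ml = blood_volume(m$thb_mass_g[i], m$hb_g_l[i]),
                            rcv_ml = NA_real_, pv_ml = NA_real_,
                            cell_factor = 0.91))
        volume_set(m$thb_mass_g[i], m$hb_g_l[i], hct[i])
      })
      volumes <- cbind(subject_id = m$subject_id, do.call(rbind, vols))
    }
  }
  structure(list(
    qc = qc$report, timecourse = tc, summary = summ,
    contrast = contrast, anova = anova, volumes = volumes,
    provenance = list(
      package_version = as.character(utils::packageVersion("ocor")),
      n_sessions = length(sessions), n_valid = length(qc$valid),
      params_hash = config_hash(params), policy_hash = config_hash(policy)
    )
  ), class = "ocor_results")
}

#' Write a results bundle to disk
#'
#' @param results an `ocor_results` bundle from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. Writes `timecourse.csv`, `qc.csv`,
#'   `summary.csv`, `volumes.csv` (when present) and `analysis.json`
#'   (contrast, ANOVA, provenance).
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results$timecourse, file.path(dir, "timecourse.csv"),
                   row.names = FALSE)
  utils::write.csv(results$qc, file.path(dir, "qc.csv"), row.names = FALSE)
  if (!is.null(results$summary))
    utils::write.csv(results$summary, file.path(dir, "summary.csv"),
                     row.names = FALSE)
  if (!is.null(results$volumes))
    utils::write.csv(results$volumes, file.path(dir, "volumes.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(contrast = results$contrast, anova = results$anova,
         provenance = results$provenance),
    file.path(dir, "analysis.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Recompute the published cohort summaries from the packaged fixture
#'
#' Runs the package's own summary machinery over the transcribed per-patient
#' values and compares each computed statistic with the printed one at the
#' printed precision.
#'
#' @param fixture a [study_fixture()].
#' @return data.frame: `statistic`, `published_value`, `computed`, `match`.
#' @export
reproduce_study <- function(fixture = study_fixture()) {
  cs <- cohort_summary(fixture$table1)
  qc <- filter_cohort(sessions_from_fixture(fixture))
  tp <- fixture$timepoint_means
  diff_7_20 <- tp$thb_mean_g[tp$time_min == 20] - tp$thb_mean_g[tp$time_min == 7]
  dosing <- reproduce_dosing(fixture)
  rows <- list(
    c("mean CO dose (ml/kg)",            0.73,  cs$dose_ml_per_kg_mean, 0.005),
    c("mean CO dose (ml)",               57.23, cs$dose_ml_mean,        0.005),
    c("mean tHb-mass (g)",               647.3, cs$thb_mean_g,          0.05),
    c("median [Hb] (g/l)",               113.0, cs$hb_median,           0.05),
    c("[Hb] lower quartile (g/l)",       100.5, cs$hb_q1,               0.05),
    c("[Hb] upper quartile (g/l)",       126.5, cs$hb_q3,               0.05),
    c("mean 7-min deltaCOHb (%)",        5.26,  cs$delta_cohb_mean,     0.005),
    c("anemic patients (n)",             10,    cs$anemic_n,            0),
    c("anemic patients (%)",             77,    round(cs$anemic_pct),   0),
    c("anemic subgroup mean [Hb] (g/l)", 107,   cs$anemic_hb_mean,      0.5),
    c("non-anemic mean [Hb] (g/l)",      153.3, cs$nonanemic_hb_mean,   0.05),
    c("sessions excluded (deltaCOHb < 4%)", 3,  sum(!qc$report$valid),  0),
    c("males dosed at 0.8 ml/kg (n)",    4,     unname(cs$male_dose_counts["0.8"]), 0),
    c("males dosed at 0.8 ml/kg (%)",    36,    round(cs$male_pct_at["0.8"]), 0),
    c("tHb-mass difference 7 vs 20 min (g)", 4.1, diff_7_20,            0.05),
    c("published ml/kg doses reproduced (n of 13)", 13, sum(dosing$match), 0)
  )
  out <- data.frame(
    statistic = vapply(rows, `[[`, character(1), 1),
    published_value = as.numeric(vapply(rows, `[[`, character(1), 2)),
    computed = as.numeric(vapply(rows, `[[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  tol <- as.numeric(vapply(rows, `[[`, character(1), 4))
  out$match <- abs(out$computed - out$published_value) <= tol + 1e-9
  out
}
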