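#' tHb-mass at every sampling time of a session
#'
#' Computes one tHb-mass estimate per requested time; the symbolic 7-min
#' entry uses the mean of the 6- and 8-min COHb readings with losses
#' evaluated at t = 7. Times whose sample is missing (or whose rise is
#' non-positive) yield a flagged row with `NA` mass rather than an error.
#'
#' @param session an [ocor_session()].
#' @param times sampling times in minutes; 7 denotes the symbolic 7-min
#'   value. Default `c(6, 7, 8, 10, 12, 15, 20)`.
#' @param params a [correction_params()].
#' @return data.frame with one row per requested time: `subject_id`,
#'   `time_min`, `cohb_pct`, `delta_cohb_pct`, `absorbed_co_ml`,
#'   `thb_mass_g`, `flags`.
#' @export
thb_timecourse <- function(session, times = c(6, 7, 8, 10, 12, 15, 20),
                           params = correction_params()) {
  rows <- lapply(times, function(tm) {
    cohb <- tryCatch(
      if (identical(as.numeric(tm), 7)) seven_min_cohb(session)
      else cohb_at(session, tm),
      ocor_missing_timepoint = function(e) NA_real_)
    if (is.na(cohb))
      return(data.frame(time_min = as.numeric(tm), cohb_pct = NA_real_,
                        delta_cohb_pct = NA_real_, absorbed_co_ml = NA_real_,
                        thb_mass_g = NA_real_, flags = "MISSING_TIMEPOINT",
                        stringsAsFactors = FALSE))
    res <- tryCatch(thb_mass_at(session, tm, params),
                    ocor_invalid_rise = function(e)
                      data.frame(time_min = as.numeric(tm),
                                 delta_cohb_pct = cohb - baseline_cohb(session),
                                 absorbed_co_ml = NA_real_,
                                 thb_mass_g = NA_real_, flags = "NEGATIVE_DELTA",
                                 stringsAsFactors = FALSE))
    cbind(res[, "time_min", drop = FALSE], cohb_pct = cohb,
          res[, setdiff(names(res), "time_min"), drop = FALSE])
  })
  out <- do.call(rbind, rows)
  cbind(subject_id = session$subject_id, out, stringsAsFactors = FALSE)
}

#' Run the timecourse over a cohort
#'
#' @param sessions list of [ocor_session()] objects.
#' @inheritParams thb_timecourse
#' @return long data.frame of row-bound [thb_timecourse()] results.
#' @export
cohort_timecourse <- function(sessions, times = c(6, 7, 8, 10, 12, 15, 20),
                              params = correction_params()) {
  do.call(rbind, lapply(sessions, thb_timecourse, times = times, params = params))
}

#' Tukey quartiles (midpoint-of-halves)
#'
#' Lower/upper quartile as the median of the lower/upper half of the sorted
#' data, the median itself excluded when n is odd. This is the convention
#' that reproduces published interquartile ranges for small clinical cohorts.
#'
#' @param x numeric vector.
#' @return named vector `c(q1, median, q3)`.
#' @export
tukey_quartiles <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 2) ocor_abort("ocor_domain_error", "need at least 2 values")
  half <- floor(n / 2)
  lower <- x[seq_len(half)]
  upper <- x[seq.int(n - half + 1L, n)]
  c(q1 = stats::median(lower), median = stats::median(x),
    q3 = stats::median(upper))
}

#' Per-timepoint cohort summaries
#'
#' For each time on the grid: median and Tukey quartiles of COHb%, and mean
#' and sample SD (n - 1) of tHb-mass, over the subjects with data at that
#' time.
#'
#' @param results long data.frame from [cohort_timecourse()].
#' @param times time grid to summarize. Default: all times present.
#' @return data.frame with one row per time: `time_min`, `n`,
#'   `cohb_median`, `cohb_q1`, `cohb_q3`, `thb_mean_g`, `thb_sd_g`.
#' @export
timepoint_summary <- function(results, times = sort(unique(results$time_min))) {
  if (!nrow(results) || length(unique(results$subject_id)) < 2)
    ocor_abort("ocor_domain_error", "need at least 2 subjects to summarize")
  rows <- lapply(times, function(tm) {
    r <- results[results$time_min == tm & !is.na(results$thb_mass_g), ]
    q <- tukey_quartiles(r$cohb_pct)
    data.frame(time_min = tm, n = nrow(r),
               cohb_median = unname(q["median"]), cohb_q1 = unname(q["q1"]),
               cohb_q3 = unname(q["q3"]),
               thb_mean_g = mean(r$thb_mass_g), thb_sd_g = stats::sd(r$thb_mass_g))
  })
  do.call(rbind, rows)
}

#' Paired contrast of tHb-mass between two sampling times
#'
#' Mean difference (comparison minus reference) over subjects with both
#' timepoints, the difference as a percent of the reference mean, and a
#' two-sided paired t test (closed form, Student t with n - 1 df). When every
#' paired difference is identical the t statistic is degenerate: a zero mean
#' difference returns p = 1, a non-zero one returns p = 0 with a
#' `degenerate_variance` flag.
#'
#' @param results long data.frame from [cohort_timecourse()].
#' @param ref_time,cmp_time reference and comparison times, minutes.
#' @return list: `ref_time`, `cmp_time`, `n`, `mean_diff_g`, `pct_diff`,
#'   `t`, `df`, `p_value`, `degenerate_variance`.
#' @export
paired_contrast <- function(results, ref_time = 7, cmp_time = 20) {
  a <- results[results$time_min == ref_time, c("subject_id", "thb_mass_g")]
  b <- results[results$time_min == cmp_time, c("subject_id", "thb_mass_g")]
  m <- merge(a, b, by = "subject_id", suffixes = c("_ref", "_cmp"))
  m <- m[stats::complete.cases(m), ]
  n <- nrow(m)
  if (n < 2)
    ocor_abort("ocor_domain_error", "need at least 2 complete pairs")
  d <- m$thb_mass_g_cmp - m$thb_mass_g_ref
  md <- mean(d)
  s <- stats::sd(d)
  degenerate <- s == 0
  if (degenerate) {
    tstat <- if (md == 0) 0 else Inf * sign(md)
    p <- if (md == 0) 1 else 0
  } else {
    tstat <- md / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  }
  list(ref_time = ref_time, cmp_time = cmp_time, n = n,
       mean_diff_g = md, pct_diff = 100 * md / mean(m$thb_mass_g_ref),
       t = tstat, df = n - 1, p_value = p, degenerate_variance = degenerate)
}

#' One-way repeated-measures ANOVA across the time grid
#'
#' Within-subject F test for a time effect on tHb-mass: subjects are blocks,
#' `F = MS_time / MS_error` with (k - 1) and (n - 1)(k - 1) degrees of
#' freedom. Subjects missing any grid time are dropped (listwise deletion).
#' A zero time effect with zero error mean square returns F = 0, p = 1; a
#' positive time effect with zero error returns F = Inf, p = 0.
#'
#' @param results long data.frame from [cohort_timecourse()].
#' @param times time grid; default the measured grid
#'   `c(6, 8, 10, 12, 15, 20)`.
#' @return list: `F`, `df1`, `df2`, `p_value`, `n`, `k`, plus the sums of
#'   squares `ss_time`, `ss_subject`, `ss_error`.
#' @export
repeated_measures_anova <- function(results, times = c(6, 8, 10, 12, 15, 20)) {
  r <- results[results$time_min %in% times & !is.na(results$thb_mass_g), ]
  wide <- stats::reshape(r[, c("subject_id", "time_min", "thb_mass_g")],
                         idvar = "subject_id", timevar = "time_min",
                         direction = "wide")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  y <- as.matrix(wide[, -1, drop = FALSE])
  n <- nrow(y); k <- ncol(y)
  if (n < 2 || k < 2)
    ocor_abort("ocor_domain_error", "need >= 2 complete subjects and >= 2 times")
  grand <- mean(y)
  ss_time <- n * sum((colMeans(y) - grand)^2)
  ss_subject <- k * sum((rowMeans(y) - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_error <- ss_total - ss_time - ss_subject
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  ms_time <- ss_time / df1
  ms_error <- ss_error / df2
  eps <- 1e-12 * max(ss_total, 1)
  if (ms_error <= eps) {
    f <- if (ms_time <= eps) 0 else Inf
    p <- if (ms_time <= eps) 1 else 0
  } else {
    f <- ms_time / ms_error
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(F = f, df1 = df1, df2 = df2, p_value = p, n = n, k = k,
       ss_time = ss_time, ss_subject = ss_subject, ss_error = ss_error)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper around [stats::shapiro.test()] with the domain guards this
#' pipeline needs (3 <= n <= 50; constant input is a domain error rather than
#' a cryptic failure).
#'
#' @param values numeric vector.
#' @return list: `W`, `p_value`, `n`.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 50)
    ocor_abort("ocor_domain_error", sprintf("n = %d outside [3, 50]", n))
  if (stats::sd(values) == 0)
    ocor_abort("ocor_domain_error", "values are constant (zero variance)")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p_value = sw$p.value, n = n)
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided test of COHb% differences between timepoints, as used in the
#' study design this pipeline reproduces (the groups are the per-subject
#' values at each time, treated as unpaired). The U statistic for the first
#' group is computed from ranks; the p-value is exact (full permutation
#' distribution) when both groups have at most `exact_max` observations and
#' there are no ties, and a tie-corrected normal approximation otherwise,
#' via [stats::wilcox.test()].
#'
#' @param group_a,group_b numeric vectors.
#' @param exact_max largest per-group n for the exact path. Default 8.
#' @return list: `U`, `p_value`, `exact` (logical).
#' @export
mann_whitney <- function(group_a, group_b, exact_max = 8) {
  if (!length(group_a) || !length(group_b))
    ocor_abort("ocor_domain_error", "both groups must be non-empty")
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- length(group_a) <= exact_max && length(group_b) <= exact_max && !ties
  rk <- rank(c(group_a, group_b))
  na <- length(group_a)
  u_a <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = exact,
                                            correct = TRUE))
  list(U = unname(u_a), p_value = wt$p.value, exact = exact)
}

#' Cohort summary in the style of a study demographics table
#'
#' @param cohort data.frame with one row per analysed subject and columns
#'   `sex` ("male"/"female"), `hb_g_l`, `thb_mass_g`, `dose_co_ml`,
#'   `dose_ml_per_kg`, `delta_cohb7_pct`.
#' @return list of summary statistics: dose means/SDs, tHb-mass mean/SD,
#'   \[Hb\] median and Tukey quartiles, WHO anemia count/percent and subgroup
#'   \[Hb\] means, delta COHb mean, and the count/percent of males at each
#'   ml/kg dose level.
#' @export
cohort_summary <- function(cohort) {
  if (!nrow(cohort)) ocor_abort("ocor_domain_error", "empty cohort")
  anemic <- mapply(classify_anemia, cohort$hb_g_l, cohort$sex)
  q <- tukey_quartiles(cohort$hb_g_l)
  males <- cohort[cohort$sex == "male", ]
  male_dose_counts <- table(factor(males$dose_ml_per_kg))
  list(
    n = nrow(cohort),
    dose_ml_mean = mean(cohort$dose_co_ml), dose_ml_sd = stats::sd(cohort$dose_co_ml),
    dose_ml_per_kg_mean = mean(cohort$dose_ml_per_kg),
    dose_ml_per_kg_sd = stats::sd(cohort$dose_ml_per_kg),
    thb_mean_g = mean(cohort$thb_mass_g), thb_sd_g = stats::sd(cohort$thb_mass_g),
    hb_median = unname(q["median"]), hb_q1 = unname(q["q1"]), hb_q3 = unname(q["q3"]),
    delta_cohb_mean = mean(cohort$delta_cohb7_pct),
    delta_cohb_sd = stats::sd(cohort$delta_cohb7_pct),
    anemic_n = sum(anemic),
    anemic_pct = 100 * sum(anemic) / nrow(cohort),
    anemic_hb_mean = mean(cohort$hb_g_l[anemic]),
    nonanemic_hb_mean = mean(cohort$hb_g_l[!anemic]),
    n_male = nrow(males),
    male_dose_counts = male_dose_counts,
    male_pct_at = stats::setNames(100 * as.numeric(male_dose_counts) / nrow(males),
                                  names(male_dose_counts))
  )
}
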