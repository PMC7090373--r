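#' Simulation configuration for synthetic rebreathing cohorts
#'
#' Defaults emulate a chronic-liver-disease cohort: true tHb-mass 650 +/- 150
#' g (truncated above 200 g), expanded plasma volume 4200 +/- 1100 ml
#' (truncated above 2000 ml), baseline COHb 1.62 +/- 0.77% (truncated at
#' 0.3%; cirrhosis raises baseline COHb via heme-oxygenase CO production),
#' ~11:13 male, ages 52 +/- 13.8 y, mass 79.1 +/- 11.4 kg, height 175 +/- 6.8
#' cm. \[Hb\] is derived from true tHb-mass and true blood volume, which at
#' these defaults yields a WHO-anemia prevalence of roughly three quarters.
#'
#' @param n_subjects cohort size. Default 13.
#' @param seed RNG seed consumed by [simulate_cohort()].
#' @param thb_mean,thb_sd,thb_min true tHb-mass distribution, g. `thb_mean`
#'   and `thb_sd` are per-sex (named vectors): women carry substantially less
#'   haemoglobin mass than men, which is what sex-specific CO dosing
#'   compensates for. At the default male fraction the mixture has mean
#'   ~650 g and SD ~150 g.
#' @param pv_mean,pv_sd,pv_min true plasma-volume distribution, ml (expanded
#'   in diuretic-refractory ascites; the default centres derived \[Hb\] near
#'   the published median of 113 g/l).
#' @param thb_weight_cor correlation between true tHb-mass and body mass.
#'   Default 0.6: tHb-mass scales with (lean) body mass, which is why CO
#'   doses are weight-indexed at all.
#' @param mchc_g_l mean corpuscular Hb concentration used to convert true
#'   tHb-mass to red-cell volume, g/l. Default 340.
#' @param cell_factor body-to-venous hematocrit ratio. Default 0.91.
#' @param baseline_mean,baseline_sd,baseline_min baseline COHb distribution,
#'   percent.
#' @param p_male probability a simulated subject is male. Default 11/13.
#' @param age_mean,age_sd,weight_mean,weight_sd,height_mean,height_sd
#'   covariate distributions (years, kg, cm); weight and height are per-sex
#'   with mixture moments matching the published cohort (79.1 +/- 11.4 kg,
#'   175 +/- 6.8 cm).
#' @param tau_min mixing time constant of the exponential wash-in, minutes.
#'   Default 1.2.
#' @param lag_min uptake lag before COHb starts rising, minutes. Default 0.5.
#' @param mix_complete_min time at which circulatory mixing is complete,
#'   minutes; the wash-in reaches its asymptote exactly here. Default 6 (the
#'   first sampling time).
#' @param exhale_range per-subject CO exhalation rate range (uniform),
#'   ml/min. Default c(0.06, 0.28), spanning 1.0-5.1 ml over 18 min.
#' @param k_myo_per_min myoglobin uptake rate, per minute of dose. Default
#'   0.00175.
#' @param residual_fraction fraction of the administered dose left in the
#'   spirometer and lung at disconnection. Default 0.12.
#' @param noise_sd per-replicate hemoximeter noise SD, percentage points.
#'   Default 0.10.
#' @param resolution hemoximeter reading resolution, percentage points
#'   (0 disables quantization). Default 0.1.
#' @param replicates hemoximeter replicates per blood sample. Default 2.
#' @param grid sampling grid, minutes; 0 denotes the baseline draw. Default
#'   `c(0, 6, 8, 10, 12, 15, 20)`.
#' @param policy [dosing_policy()] used to assign each subject's CO dose.
#' @param anemia_reduction_prob probability that the (discretionary) anemia
#'   dose reduction is actually applied to an anemic subject. Default 0.5,
#'   emulating investigator discretion: in practice the reduction is waived
#'   about as often as it is applied. At this default the simulated mean dose
#'   is ~0.73 ml/kg.
#' @param max_delta_inf_pct largest feasible asymptotic COHb rise, percent;
#'   a subject whose assigned dose would exceed it triggers a
#'   regenerate-dose error. Default 12.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 13, seed = 1L,
                       thb_mean = c(male = 675, female = 490),
                       thb_sd = c(male = 140, female = 110),
                       thb_min = 200,
                       thb_weight_cor = 0.6,
                       pv_mean = 4400, pv_sd = 1100, pv_min = 2000,
                       mchc_g_l = 340, cell_factor = 0.91,
                       baseline_mean = 1.62, baseline_sd = 0.77,
                       baseline_min = 0.3,
                       p_male = 11 / 13,
                       age_mean = 52, age_sd = 13.8,
                       weight_mean = c(male = 81.5, female = 66),
                       weight_sd = c(male = 10.5, female = 9),
                       height_mean = c(male = 177, female = 164),
                       height_sd = c(male = 6, female = 6),
                       tau_min = 1.2, lag_min = 0.5, mix_complete_min = 6,
                       exhale_range = c(0.06, 0.28),
                       k_myo_per_min = 0.00175,
                       residual_fraction = 0.12,
                       noise_sd = 0.10, resolution = 0.1, replicates = 2L,
                       grid = c(0, 6, 8, 10, 12, 15, 20),
                       policy = dosing_policy(),
                       anemia_reduction_prob = 0.5,
                       max_delta_inf_pct = 12) {
  if (tau_min <= 0) ocor_abort("ocor_config_error", "tau_min must be positive")
  if (is.unsorted(grid, strictly = TRUE))
    ocor_abort("ocor_config_error", "grid must be strictly increasing")
  if (noise_sd < 0 || resolution < 0)
    ocor_abort("ocor_config_error", "noise_sd and resolution must be >= 0")
  structure(as.list(environment()), class = "sim_config")
}

# truncated-normal draw by rejection (draws are cheap at these truncations)
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Draw one synthetic subject with ground truth
#'
#' Draws covariates and the latent physiology (true tHb-mass, plasma volume),
#' derives \[Hb\] and hematocrit from them, and assigns a CO dose via
#' [recommend_dose()]. Consumes the current RNG state; seed via `set.seed()`
#' or use [simulate_cohort()].
#'
#' @param config a [sim_config()].
#' @param id subject identifier. Default "s1".
#' @return list with `subject` (an [ocor_subject()]) and `truth` (one-row
#'   data.frame of latent values sufficient to recompute the noise-free
#'   wash-in exactly).
#' @export
simulate_subject <- function(config = sim_config(), id = "s1") {
  sex <- if (stats::runif(1) < config$p_male) "male" else "female"
  by_sex <- function(x) if (length(x) == 1) unname(x) else unname(x[sex])
  age <- rnorm_trunc(1, config$age_mean, config$age_sd, 18, 95)
  height <- rnorm_trunc(1, by_sex(config$height_mean), by_sex(config$height_sd),
                        140, 210)
  weight <- rnorm_trunc(1, by_sex(config$weight_mean), by_sex(config$weight_sd),
                        40, 140)
  # tHb-mass correlated with body mass within sex
  rho <- config$thb_weight_cor
  z_w <- (weight - by_sex(config$weight_mean)) / by_sex(config$weight_sd)
  thb <- rnorm_trunc(1, by_sex(config$thb_mean) + by_sex(config$thb_sd) * rho * z_w,
                     by_sex(config$thb_sd) * sqrt(1 - rho^2), config$thb_min)
  pv <- rnorm_trunc(1, config$pv_mean, config$pv_sd, config$pv_min)
  rcv <- thb / (config$mchc_g_l / 1000)         # g / (g/ml) -> ml
  bv <- rcv + pv
  hb <- thb * 1000 / (config$cell_factor * bv)  # inverts blood_volume()
  hct <- rcv / (bv * config$cell_factor)        # inverts red_cell_volume()
  baseline <- rnorm_trunc(1, config$baseline_mean, config$baseline_sd,
                          config$baseline_min)
  # performance status: most patients ambulant but restricted; ~15% fully
  # active, ~25% at or beyond the dose-reduction threshold
  ps <- sample(0:3, 1, prob = c(0.15, 0.60, 0.17, 0.08))
  subject <- ocor_subject(id, sex, weight_kg = weight, height_cm = height,
                          hb_g_l = hb, age_y = age, hct = hct,
                          performance_status = ps,
                          training_status = "debilitated",
                          polycythemia = hb > 175)
  # the anemia reduction is discretionary in practice: waive it at random
  anemic <- classify_anemia(hb, sex)
  reduce <- if (anemic) stats::runif(1) < config$anemia_reduction_prob else NA
  rec <- recommend_dose(subject, config$policy, apply_anemia_reduction = reduce)
  exhale <- stats::runif(1, config$exhale_range[1], config$exhale_range[2])
  truth <- data.frame(
    subject_id = subject$id, sex = sex,
    thb_true_g = thb, pv_true_ml = pv, rcv_true_ml = rcv, bv_true_ml = bv,
    hb_g_l = hb, hct = hct, baseline_true_pct = baseline,
    exhale_rate_ml_per_min = exhale,
    dose_ml = rec$dose_ml, dose_ml_per_kg = rec$ml_per_kg,
    weight_kg = weight, stringsAsFactors = FALSE
  )
  list(subject = subject, truth = truth)
}

# fraction of the CO bolus mixed into venous blood at time t: exponential
# approach, normalized to reach exactly 1 at mix_complete_min and clamped
# there (mixing is complete at the first sampling time by construction)
mixing_fraction <- function(t, config) {
  raw <- 1 - exp(-pmax(0, t - config$lag_min) / config$tau_min)
  full <- 1 - exp(-(config$mix_complete_min - config$lag_min) / config$tau_min)
  pmin(1, raw / full)
}

#' Simulate one wash-in session from a subject's ground truth
#'
#' The noise-free venous COHb curve is
#' `baseline + dCOHb_inf * m(t) - 100 * losses(t) / (huefner * tHb_true)`,
#' where `dCOHb_inf = M_CO_available * 100 / (huefner * tHb_true)`,
#' `M_CO_available` is the dose minus the spirometer/lung residual, `m(t)`
#' the mixing fraction, and `losses(t)` the exhaled + myoglobin CO of the
#' same linear loss model the calculator reverses. Per-replicate Gaussian
#' noise and quantization to the hemoximeter resolution are then applied.
#'
#' @param truth one-row truth data.frame from [simulate_subject()].
#' @param config a [sim_config()].
#' @return an [ocor_session()]; errors with class `ocor_dose_error` when the
#'   assigned dose would push the asymptotic rise above
#'   `config$max_delta_inf_pct` (caller should redraw the subject).
#' @export
simulate_washin <- function(truth, config = sim_config()) {
  dose <- truth$dose_ml
  residual <- config$residual_fraction * dose
  available <- dose - residual
  huefner <- 1.39
  d_inf <- available * 100 / (huefner * truth$thb_true_g)
  if (d_inf > config$max_delta_inf_pct)
    ocor_abort("ocor_dose_error",
               sprintf("asymptotic rise %.1f%% exceeds %.1f%%: regenerate dose",
                       d_inf, config$max_delta_inf_pct))
  tgrid <- config$grid[config$grid > 0]
  losses <- config$k_myo_per_min * dose * tgrid +
    truth$exhale_rate_ml_per_min * pmax(0, tgrid - 2)
  cohb_nf <- truth$baseline_true_pct +
    d_inf * mixing_fraction(tgrid, config) -
    100 * losses / (huefner * truth$thb_true_g)
  times <- c(rep(-1, config$replicates),
             rep(tgrid, each = config$replicates))
  clean <- c(rep(truth$baseline_true_pct, config$replicates),
             rep(cohb_nf, each = config$replicates))
  noisy <- clean + stats::rnorm(length(clean), 0, config$noise_sd)
  if (config$resolution > 0)
    noisy <- round(noisy / config$resolution) * config$resolution
  noisy <- pmin(pmax(noisy, 0), 100)
  ocor_session(truth$subject_id, dose_co_ml = dose,
               samples = data.frame(time_min = times, cohb_pct = noisy),
               rebreathe_end_min = 2,
               residual_system_co_ml = residual,
               exhale_rate_ml_per_min = truth$exhale_rate_ml_per_min,
               weight_kg = truth$weight_kg,
               dose_ml_per_kg = truth$dose_ml_per_kg)
}

#' Simulate a full seeded cohort
#'
#' Seeds the RNG from `config$seed`, then draws subjects and their wash-in
#' sessions. A subject whose dose is infeasible for their (rare, very low)
#' true tHb-mass is redrawn, mirroring the clinical protocol of re-dosing.
#'
#' @param config a [sim_config()].
#' @param max_retries redraw budget per subject slot. Default 50.
#' @return list: `sessions` (list of [ocor_session()]), `truth` (data.frame,
#'   one row per subject), `subjects` (list of [ocor_subject()]).
#' @export
simulate_cohort <- function(config = sim_config(), max_retries = 50L) {
  set.seed(config$seed)
  sessions <- vector("list", config$n_subjects)
  subjects <- vector("list", config$n_subjects)
  truths <- vector("list", config$n_subjects)
  if (config$n_subjects == 0)
    return(list(sessions = list(), truth = data.frame(), subjects = list()))
  for (i in seq_len(config$n_subjects)) {
    for (attempt in seq_len(max_retries)) {
      draw <- simulate_subject(config, id = sprintf("s%02d", i))
      sess <- tryCatch(simulate_washin(draw$truth, config),
                       ocor_dose_error = function(e) NULL)
      if (!is.null(sess)) break
      sess <- NULL
    }
    if (is.null(sess))
      ocor_abort("ocor_dose_error",
                 sprintf("could not draw a feasible subject for slot %d", i))
    sessions[[i]] <- sess
    subjects[[i]] <- draw$subject
    truths[[i]] <- draw$truth
  }
  list(sessions = sessions, truth = do.call(rbind, truths), subjects = subjects)
}
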