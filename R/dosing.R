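#' Construct a subject record
#'
#' Covariates feeding CO dose planning and volume derivatives.
#'
#' @param id identifier.
#' @param sex "male" or "female".
#' @param weight_kg,height_cm body mass (kg) and height (cm); positive.
#' @param hb_g_l venous haemoglobin concentration, g/l; positive.
#' @param age_y years (optional).
#' @param hct venous hematocrit, fraction in (0, 1) (optional).
#' @param performance_status Zubrod/WHO performance status, integer 0 (fully
#'   active) to 5.
#' @param training_status one of "trained", "untrained", "debilitated".
#'   Chronic-disease cohorts are usually "debilitated" (deconditioned beyond
#'   merely untrained).
#' @param polycythemia flag; polycythemic subjects need a larger CO dose to
#'   achieve the target COHb rise.
#' @return object of class `ocor_subject`.
#' @export
ocor_subject <- function(id, sex, weight_kg, height_cm, hb_g_l,
                         age_y = NA_real_, hct = NA_real_,
                         performance_status = 1L,
                         training_status = c("debilitated", "untrained", "trained"),
                         polycythemia = FALSE) {
  sex <- match.arg(sex, c("male", "female"))
  training_status <- match.arg(training_status)
  if (weight_kg <= 0 || height_cm <= 0)
    ocor_abort("ocor_domain_error", "weight_kg and height_cm must be positive")
  if (hb_g_l <= 0)
    ocor_abort("ocor_domain_error", "hb_g_l must be positive")
  if (performance_status < 0 || performance_status > 5)
    ocor_abort("ocor_domain_error", "performance_status must be in 0..5")
  if (!is.na(hct) && (hct <= 0 || hct >= 1))
    ocor_abort("ocor_domain_error", "hct must be a fraction in (0, 1)")
  structure(list(
    id = as.character(id), sex = sex, age_y = age_y,
    weight_kg = weight_kg, height_cm = height_cm, hb_g_l = hb_g_l,
    hct = hct, performance_status = as.integer(performance_status),
    training_status = training_status, polycythemia = isTRUE(polycythemia)
  ), class = "ocor_subject")
}

#' WHO anemia classification
#'
#' Anemia is \[Hb\] < 130 g/l in males and < 120 g/l in non-pregnant females
#' (strict inequalities).
#'
#' @param hb_g_l venous haemoglobin concentration, g/l.
#' @param sex "male" or "female".
#' @return logical.
#' @export
classify_anemia <- function(hb_g_l, sex) {
  if (any(hb_g_l <= 0))
    ocor_abort("ocor_domain_error", "hb_g_l must be positive")
  sex <- match.arg(sex, c("male", "female"))
  hb_g_l < if (sex == "male") 130 else 120
}

#' Body mass index, kg/m^2, to one decimal
#'
#' @param weight_kg body mass, kg.
#' @param height_cm height, cm.
#' @export
bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    ocor_abort("ocor_domain_error", "weight and height must be positive")
  round(weight_kg / (height_cm / 100)^2, 1)
}

#' Ideal body weight (Devine formula), kg
#'
#' Male: 50 + 2.3 kg per inch over 60 in; female: 45.5 + 2.3 kg per inch over
#' 60 in; floored at the base value for heights at or below 60 in.
#'
#' @param height_cm height, cm.
#' @param sex "male" or "female".
#' @export
ideal_body_weight <- function(height_cm, sex) {
  sex <- match.arg(sex, c("male", "female"))
  base <- if (sex == "male") 50 else 45.5
  base + 2.3 * pmax(0, height_cm / 2.54 - 60)
}

#' Dosing policy
#'
#' The rule set and knobs behind [recommend_dose()].
#'
#' @param base_ml_per_kg named base doses by sex and training status, ml/kg.
#'   Defaults: trained male 1.0, untrained/debilitated male 0.8, trained
#'   female 0.7, untrained/debilitated female 0.6.
#' @param step_ml_per_kg size of each adjustment step, ml/kg. Default 0.1
#'   (every dose in clinical use is a multiple of 0.1 ml/kg).
#' @param range_ml_per_kg clamp for the final weight-indexed dose. Default
#'   c(0.4, 1.0), the range safely used in patients.
#' @param anemia_reduction apply a one-step reduction for WHO anemia by
#'   default (individual subjects may override; the reduction is
#'   discretionary in practice).
#' @param ps_reduction_threshold performance status at or above which a
#'   further one-step reduction applies. Default 2.
#' @param fit_uplift_ps0 apply a one-step uplift for subjects with
#'   performance status 0 ("not debilitated"). Default TRUE.
#' @param bmi_ibw_threshold BMI above which dosing uses ideal rather than
#'   actual body weight. Default 30 kg/m^2.
#' @param syringe_resolution_ml rounding of the absolute dose, ml. Default 1.
#' @return list of class `dosing_policy`.
#' @export
dosing_policy <- function(base_ml_per_kg = c(male_trained = 1.0,
                                             male_untrained = 0.8,
                                             female_trained = 0.7,
                                             female_untrained = 0.6),
                          step_ml_per_kg = 0.1,
                          range_ml_per_kg = c(0.4, 1.0),
                          anemia_reduction = TRUE,
                          ps_reduction_threshold = 2L,
                          fit_uplift_ps0 = TRUE,
                          bmi_ibw_threshold = 30,
                          syringe_resolution_ml = 1) {
  structure(list(
    base_ml_per_kg = base_ml_per_kg,
    step_ml_per_kg = step_ml_per_kg,
    range_ml_per_kg = range_ml_per_kg,
    anemia_reduction = anemia_reduction,
    ps_reduction_threshold = as.integer(ps_reduction_threshold),
    fit_uplift_ps0 = fit_uplift_ps0,
    bmi_ibw_threshold = bmi_ibw_threshold,
    syringe_resolution_ml = syringe_resolution_ml
  ), class = "dosing_policy")
}

#' Recommend a CO dose for a subject
#'
#' Rule hierarchy, each step appended to an auditable rationale trace:
#' \enumerate{
#'   \item base dose by sex and training status ("untrained" and
#'     "debilitated" share the lower base);
#'   \item polycythemia raises the dose to the 1.0 ml/kg cap; otherwise a
#'     performance status of 0 with the policy's fit-uplift flag raises it
#'     one step;
#'   \item WHO anemia lowers it one step (default-on, overridable per
#'     subject: the reduction is at the investigator's discretion);
#'   \item performance status at or above the policy threshold lowers it one
#'     further step;
#'   \item any extra discretionary steps recorded for the subject are
#'     applied;
#'   \item clamp to the policy range; basis weight is ideal body weight when
#'     BMI exceeds the policy threshold, else actual weight; the absolute
#'     dose is rounded to the syringe resolution.
#' }
#'
#' @param subject an [ocor_subject()].
#' @param policy a [dosing_policy()].
#' @param apply_anemia_reduction per-subject override of the policy's anemia
#'   reduction: `NA` (default) follows the policy for anemic subjects; `TRUE`
#'   forces the reduction regardless of \[Hb\]; `FALSE` suppresses it.
#' @param extra_steps additional signed discretionary steps (integer,
#'   multiples of `step_ml_per_kg`), e.g. -1 for one further reduction.
#' @return list of class `dose_recommendation`: `ml_per_kg`, `dose_ml`,
#'   `basis_weight_kg`, `adjustments` (character trace).
#' @export
recommend_dose <- function(subject, policy = dosing_policy(),
                           apply_anemia_reduction = NA,
                           extra_steps = 0L) {
  trained <- subject$training_status == "trained"
  key <- paste0(subject$sex, "_", if (trained) "trained" else "untrained")
  dose <- unname(policy$base_ml_per_kg[key])
  if (is.na(dose))
    ocor_abort("ocor_config_error", sprintf("no base dose for '%s'", key))
  trace <- sprintf("base %s %s: %.1f ml/kg", subject$sex,
                   subject$training_status, dose)
  step <- policy$step_ml_per_kg
  cap <- policy$range_ml_per_kg[2]

  if (subject$polycythemia) {
    dose <- cap
    trace <- c(trace, sprintf("polycythemia: raised to %.1f ml/kg cap", cap))
  } else if (subject$performance_status == 0L && isTRUE(policy$fit_uplift_ps0)) {
    dose <- dose + step
    trace <- c(trace, sprintf("performance status 0 (fit): +%.1f ml/kg", step))
  }

  anemic <- classify_anemia(subject$hb_g_l, subject$sex)
  reduce <- if (is.na(apply_anemia_reduction)) anemic && isTRUE(policy$anemia_reduction)
            else isTRUE(apply_anemia_reduction)
  if (reduce) {
    dose <- dose - step
    trace <- c(trace, sprintf("anemia ([Hb] %.0f g/l): -%.1f ml/kg",
                              subject$hb_g_l, step))
  }
  if (subject$performance_status >= policy$ps_reduction_threshold) {
    dose <- dose - step
    trace <- c(trace, sprintf("performance status %d >= %d: -%.1f ml/kg",
                              subject$performance_status,
                              policy$ps_reduction_threshold, step))
  }
  if (extra_steps != 0L) {
    dose <- dose + extra_steps * step
    trace <- c(trace, sprintf("discretionary: %+d step(s)", as.integer(extra_steps)))
  }
  clamped <- min(max(dose, policy$range_ml_per_kg[1]), cap)
  if (clamped != dose)
    trace <- c(trace, sprintf("clamped to [%.1f, %.1f] ml/kg",
                              policy$range_ml_per_kg[1], cap))
  dose <- clamped

  basis <- subject$weight_kg
  if (bmi(subject$weight_kg, subject$height_cm) > policy$bmi_ibw_threshold) {
    basis <- ideal_body_weight(subject$height_cm, subject$sex)
    trace <- c(trace, sprintf("BMI > %.0f: dosing on ideal body weight %.1f kg",
                              policy$bmi_ibw_threshold, basis))
  }
  res <- policy$syringe_resolution_ml
  structure(list(
    ml_per_kg = dose,
    dose_ml = round(dose * basis / res) * res,
    basis_weight_kg = basis,
    adjustments = trace
  ), class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf("<dose_recommendation: %.1f ml/kg x %.1f kg -> %g ml>\n",
              x$ml_per_kg, x$basis_weight_kg, x$dose_ml))
  for (a in x$adjustments) cat(" -", a, "\n")
  invisible(x)
}
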