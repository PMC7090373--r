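test_that("cohort simulation is fully determined by its seed", {
  a <- simulate_cohort(sim_config(n_subjects = 5, seed = 21))
  b <- simulate_cohort(sim_config(n_subjects = 5, seed = 21))
  expect_identical(a$truth, b$truth)
  expect_identical(a$sessions, b$sessions)
  c2 <- simulate_cohort(sim_config(n_subjects = 5, seed = 22))
  expect_false(identical(a$truth, c2$truth))
  empty <- simulate_cohort(sim_config(n_subjects = 0, seed = 1))
  expect_length(empty$sessions, 0)
})

test_that("generated cohorts reproduce their configured moments", {
  sim <- simulate_cohort(sim_config(n_subjects = 1000, seed = 23))
  tr <- sim$truth
  # CLT bound: SE(tHb) = 150/sqrt(1000) ~ 4.7; 3 sigma ~ 15
  expect_lt(abs(mean(tr$thb_true_g) - 650), 15)
  expect_lt(abs(sd(tr$thb_true_g) - 150), 15)
  expect_lt(abs(mean(tr$baseline_true_pct) - 1.62), 0.25)  # truncation shifts up
  anemic <- mapply(classify_anemia, tr$hb_g_l, tr$sex)
  expect_gte(mean(anemic), 0.65)
  expect_lte(mean(anemic), 0.85)
  expect_gt(mean(tr$sex == "male"), 0.75)
  expect_true(all(tr$exhale_rate_ml_per_min >= 0.06 &
                    tr$exhale_rate_ml_per_min <= 0.28))
})

test_that("noise-free wash-in is inverted exactly by the calculator", {
  sim <- simulate_cohort(sim_config(n_subjects = 25, seed = 24,
                                    noise_sd = 0, resolution = 0))
  tc <- cohort_timecourse(sim$sessions)
  truth <- sim$truth$thb_true_g[match(tc$subject_id, sim$truth$subject_id)]
  expect_equal(tc$thb_mass_g, truth, tolerance = 1e-9)
})

test_that("the noise-free curve peaks on the 6-8 min plateau and stays bounded", {
  sim <- simulate_cohort(sim_config(n_subjects = 10, seed = 25,
                                    noise_sd = 0, resolution = 0))
  for (s in sim$sessions) {
    timed <- s$samples[s$samples$time_min >= 0, ]
    peak_t <- timed$time_min[which.max(timed$cohb_pct)]
    expect_gte(peak_t, 5); expect_lte(peak_t, 9)
    # readings never exceed baseline + asymptotic rise
    tr <- sim$truth[sim$truth$subject_id == s$subject_id, ]
    d_inf <- (tr$dose_ml - s$residual_system_co_ml) * 100 / (1.39 * tr$thb_true_g)
    expect_true(all(timed$cohb_pct <= tr$baseline_true_pct + d_inf + 1e-9))
  }
})

test_that("readings are quantized to the hemoximeter resolution", {
  sim <- simulate_cohort(sim_config(n_subjects = 3, seed = 26))
  for (s in sim$sessions)
    expect_equal(s$samples$cohb_pct, round(s$samples$cohb_pct, 1))
})

test_that("an infeasible dose raises a regenerate-dose error", {
  cfg <- sim_config(seed = 27)
  truth <- data.frame(subject_id = "x", thb_true_g = 210, baseline_true_pct = 1.6,
                      exhale_rate_ml_per_min = 0.15, dose_ml = 80,
                      dose_ml_per_kg = 1.0, weight_kg = 80)
  expect_error(simulate_washin(truth, cfg), class = "ocor_dose_error")
})

test_that("simulated 20-min CO losses stay inside the published ranges", {
  sim <- simulate_cohort(sim_config(n_subjects = 200, seed = 28))
  tr <- sim$truth
  in_range <- tr$dose_ml >= 40 & tr$dose_ml <= 72
  expect_gt(sum(in_range), 100)  # most doses span the published range
  myo <- vapply(sim$sessions[in_range], function(s)
    co_loss_myoglobin(s$dose_co_ml, 20), numeric(1))
  exh <- vapply(sim$sessions[in_range], function(s)
    co_loss_exhaled(s, 20), numeric(1))
  expect_true(all(myo >= 1.4 - 1e-9 & myo <= 2.9 + 1e-9))
  expect_true(all(exh >= 1.0 - 1e-9 & exh <= 5.1 + 1e-9))
})

test_that("parameter recovery at default noise is nearly unbiased", {
  sim <- simulate_cohort(sim_config(n_subjects = 500, seed = 29))
  tc <- cohort_timecourse(sim$sessions, times = 7)
  rel <- tc$thb_mass_g / sim$truth$thb_true_g[match(tc$subject_id,
                                                    sim$truth$subject_id)] - 1
  expect_lt(abs(mean(rel)), 0.01)
  expect_lt(sd(rel), 0.03)
})

test_that("most simulated 13-subject cohorts yield at least 10 valid sessions", {
  ok <- vapply(1:100, function(i) {
    sim <- simulate_cohort(sim_config(n_subjects = 13, seed = 400 + i))
    sum(filter_cohort(sim$sessions)$report$valid) >= 10
  }, logical(1))
  expect_gte(mean(ok), 0.80)
})
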