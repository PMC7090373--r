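#!/usr/bin/env Rscript
# Parameter-recovery study: how well does the calculator recover true
# tHb-mass from noisy, quantized hemoximeter readings?
#   - noise-free: the calculator inverts the generator exactly
#   - default noise (SD 0.10 pp, 0.1 resolution, 2 replicates): per-subject
#     bias and spread of the recovered mass

suppressPackageStartupMessages(library(ocor))
dir.create("results", showWarnings = FALSE)

# exact inversion
sim0 <- simulate_cohort(sim_config(n_subjects = 500, seed = 11,
                                   noise_sd = 0, resolution = 0))
tc0 <- cohort_timecourse(sim0$sessions)
err0 <- abs(tc0$thb_mass_g /
              sim0$truth$thb_true_g[match(tc0$subject_id,
                                          sim0$truth$subject_id)] - 1)
cat(sprintf("Noise-free inversion, 500 subjects x 7 times: max |rel error| = %.2e\n",
            max(err0)))

# recovery under measurement noise
sim <- simulate_cohort(sim_config(n_subjects = 500, seed = 12))
tc <- cohort_timecourse(sim$sessions, times = 7)
truth <- sim$truth$thb_true_g[match(tc$subject_id, sim$truth$subject_id)]
rel <- tc$thb_mass_g / truth - 1
tab <- data.frame(subject_id = tc$subject_id, thb_true_g = truth,
                  thb_recovered_g = tc$thb_mass_g, rel_error = rel)
utils::write.csv(tab, "results/parameter_recovery.csv", row.names = FALSE)

cat(sprintf("Default noise, 500 subjects: bias %.3f%%, relative-error SD %.2f%%\n",
            100 * mean(rel), 100 * sd(rel)))
cat(sprintf("95%% of recovered masses within %.1f%% of truth.\n",
            100 * quantile(abs(rel), 0.95)))
cat("Wrote results/parameter_recovery.csv\n")
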