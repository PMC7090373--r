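# Build a session from baseline readings and a named list of timed readings.
# times: list(`6` = c(6.3, 6.4), `8` = 6.4, ...)
make_session <- function(baseline = 1.6, times = list(`6` = 6.6, `8` = 6.6),
                         dose = 50, ...) {
  tm <- rep(as.numeric(names(times)), lengths(times))
  ocor_session("test", dose_co_ml = dose,
               samples = data.frame(
                 time_min = c(rep(-1, length(baseline)), tm),
                 cohb_pct = c(baseline, unlist(times, use.names = FALSE))),
               ...)
}

# loss-free parameter set: turns the calculator into the bare dilution formula
params_noloss <- correction_params(k_myo_per_min = 0, exhale_rate_ml_per_min = 0)

# long results table for the statistics kernels:
# one row per (subject, time) with a given matrix of tHb values
results_from_matrix <- function(y, times = seq_len(ncol(y))) {
  data.frame(
    subject_id = rep(sprintf("s%d", seq_len(nrow(y))), each = ncol(y)),
    time_min = rep(times, nrow(y)),
    cohb_pct = NA_real_,
    thb_mass_g = as.vector(t(y))
  )
}
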