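# --- independent brute-force oracles -------------------------------------

# full-enumeration two-sided Mann-Whitney p (no ties assumed)
mw_enum_oracle <- function(a, b) {
  vals <- c(a, b); na <- length(a); nb <- length(b)
  u_obs <- sum(outer(a, b, ">"))
  mu <- na * nb / 2
  combs <- utils::combn(length(vals), na)
  u_all <- apply(combs, 2, function(idx)
    sum(outer(vals[idx], vals[-idx], ">")))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# direct sums-of-squares within-subject ANOVA on a subjects x times matrix
rm_anova_oracle <- function(y) {
  n <- nrow(y); k <- ncol(y); g <- mean(y)
  ss_t <- 0; ss_s <- 0; ss_e <- 0
  for (j in 1:k) ss_t <- ss_t + n * (mean(y[, j]) - g)^2
  for (i in 1:n) ss_s <- ss_s + k * (mean(y[i, ]) - g)^2
  for (i in 1:n) for (j in 1:k)
    ss_e <- ss_e + (y[i, j] - mean(y[i, ]) - mean(y[, j]) + g)^2
  f <- (ss_t / (k - 1)) / (ss_e / ((n - 1) * (k - 1)))
  list(F = f, p = pf(f, k - 1, (n - 1) * (k - 1), lower.tail = FALSE))
}

# --- timecourse over sessions ---------------------------------------------

test_that("a noise-free synthetic session yields identical tHb-mass at all times", {
  sim <- simulate_cohort(sim_config(n_subjects = 3, seed = 5,
                                    noise_sd = 0, resolution = 0))
  for (i in 1:3) {
    tc <- thb_timecourse(sim$sessions[[i]])
    expect_equal(nrow(tc), 7)
    expect_equal(tc$thb_mass_g, rep(sim$truth$thb_true_g[i], 7),
                 tolerance = 1e-9)
  }
})

test_that("noisy sessions give finite positive estimates; missing times are flagged", {
  sim <- simulate_cohort(sim_config(n_subjects = 2, seed = 6))
  tc <- thb_timecourse(sim$sessions[[1]], times = c(7, 20))
  expect_true(all(is.finite(tc$thb_mass_g) & tc$thb_mass_g > 0))
  s <- make_session(times = list(`6` = 6.6, `8` = 6.7))
  tc2 <- thb_timecourse(s, times = c(7, 20))
  expect_true(is.na(tc2$thb_mass_g[tc2$time_min == 20]))
  expect_match(tc2$flags[tc2$time_min == 20], "MISSING_TIMEPOINT")
  expect_false(is.na(tc2$thb_mass_g[tc2$time_min == 7]))
})

# --- summaries -------------------------------------------------------------

test_that("Tukey quartiles reproduce the published [Hb] summary", {
  hb <- study_fixture()$table1$hb_g_l
  q <- tukey_quartiles(hb)
  expect_equal(unname(q), c(100.5, 113.0, 126.5))
  expect_equal(unname(tukey_quartiles(c(3, 3, 3, 3))), c(3, 3, 3))
  expect_equal(unname(tukey_quartiles(1:4)), c(1.5, 2.5, 3.5))
})

test_that("per-timepoint summaries report median/IQR of COHb and mean/SD of tHb", {
  y <- rbind(c(600, 610), c(700, 690), c(650, 655))
  res <- results_from_matrix(y, times = c(7, 20))
  res$cohb_pct <- rep(c(6.0, 6.5, 7.0), each = 2)
  s <- timepoint_summary(res)
  expect_equal(s$time_min, c(7, 20))
  expect_equal(s$thb_mean_g, c(mean(y[, 1]), mean(y[, 2])))
  expect_equal(s$thb_sd_g, c(sd(y[, 1]), sd(y[, 2])))
  expect_equal(s$cohb_median, c(6.5, 6.5))
  expect_error(timepoint_summary(res[1:2, ]), class = "ocor_domain_error")
})

# --- paired contrast -------------------------------------------------------

test_that("paired contrast matches the closed form and the t-test oracle", {
  y <- rbind(c(600, 601), c(700, 702), c(650, 653))  # diffs 1, 2, 3
  res <- results_from_matrix(y, times = c(7, 20))
  ct <- paired_contrast(res, 7, 20)
  expect_equal(ct$mean_diff_g, 2.0)
  expect_equal(ct$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(ct$p_value, 0.0741799, tolerance = 1e-5)
  tt <- t.test(y[, 2], y[, 1], paired = TRUE)
  expect_equal(ct$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(ct$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(ct$pct_diff, 100 * 2 / mean(y[, 1]))
})

test_that("degenerate paired differences are guarded, not propagated as NaN", {
  same <- results_from_matrix(rbind(c(600, 600), c(700, 700)), times = c(7, 20))
  ct <- paired_contrast(same, 7, 20)
  expect_equal(ct$mean_diff_g, 0)
  expect_equal(ct$p_value, 1)
  shift <- results_from_matrix(rbind(c(1, 2), c(2, 3), c(3, 4)), times = c(7, 20))
  ct2 <- paired_contrast(shift, 7, 20)
  expect_equal(ct2$mean_diff_g, 1)
  expect_equal(ct2$p_value, 0)
  expect_true(ct2$degenerate_variance)
  expect_error(paired_contrast(same[1:2, ], 7, 20), class = "ocor_domain_error")
})

# --- repeated-measures ANOVA ----------------------------------------------

test_that("RM-ANOVA matches brute-force sums of squares and the lm oracle", {
  set.seed(9)
  y <- matrix(rnorm(12, 650, 20), nrow = 4, ncol = 3)
  res <- results_from_matrix(y, times = c(6, 8, 10))
  a <- repeated_measures_anova(res, times = c(6, 8, 10))
  o <- rm_anova_oracle(y)
  expect_equal(a$F, o$F, tolerance = 1e-9)
  expect_equal(a$p_value, o$p, tolerance = 1e-9)
  # independent route: two-way fixed-effects fit, time tested against residual
  long <- data.frame(y = as.vector(y),
                     s = factor(rep(1:4, 3)), t = factor(rep(1:3, each = 4)))
  tab <- anova(lm(y ~ s + t, data = long))
  expect_equal(a$F, tab["t", "F value"], tolerance = 1e-9)
  expect_equal(a$p_value, tab["t", "Pr(>F)"], tolerance = 1e-9)
})

test_that("RM-ANOVA degenerate cases: no time effect and pure subject shifts", {
  flat <- results_from_matrix(rbind(c(5, 5, 5), c(7, 7, 7)), times = 1:3)
  a <- repeated_measures_anova(flat, times = 1:3)
  expect_equal(a$F, 0)
  expect_equal(a$p_value, 1)
  # subject effects only (rows shifted, flat in time): F = 0, p = 1
  shifted <- results_from_matrix(rbind(c(1, 1, 1), c(11, 11, 11), c(21, 21, 21)),
                                 times = 1:3)
  as <- repeated_measures_anova(shifted, times = 1:3)
  expect_gt(as$ss_subject, 0)
  expect_equal(as$F, 0)
  expect_equal(as$p_value, 1)
  # consistent time trend with zero error: F diverges, p = 0
  trend <- results_from_matrix(rbind(c(1, 2, 3), c(11, 12, 13), c(21, 22, 23)),
                               times = 1:3)
  at <- repeated_measures_anova(trend, times = 1:3)
  expect_equal(at$p_value, 0)
  expect_error(repeated_measures_anova(flat[1:3, ], times = 1:3),
               class = "ocor_domain_error")
})

test_that("F equals t-squared on a two-timepoint grid", {
  set.seed(10)
  for (rep in 1:5) {
    y <- matrix(rnorm(10, 650, 30), nrow = 5, ncol = 2)
    res <- results_from_matrix(y, times = c(7, 20))
    a <- repeated_measures_anova(res, times = c(7, 20))
    ct <- paired_contrast(res, 7, 20)
    expect_equal(a$F, ct$t^2, tolerance = 1e-9)
    expect_equal(a$p_value, ct$p_value, tolerance = 1e-9)
  }
})

# --- normality and Mann-Whitney -------------------------------------------

test_that("normality check is calibrated on normal and skewed samples", {
  pass_norm <- sum(vapply(1:100, function(i) {
    set.seed(i); normality_check(rnorm(20))$p_value > 0.05
  }, logical(1)))
  expect_gte(pass_norm, 90)
  rej_exp <- sum(vapply(1:100, function(i) {
    set.seed(i); normality_check(rexp(30))$p_value < 0.05
  }, logical(1)))
  expect_gte(rej_exp, 90)
  expect_error(normality_check(rep(1, 10)), class = "ocor_domain_error")
  expect_error(normality_check(rnorm(2)), class = "ocor_domain_error")
  expect_error(normality_check(rnorm(60)), class = "ocor_domain_error")
})

test_that("Mann-Whitney matches full enumeration on small tie-free samples", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  mw <- mann_whitney(a, b)
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)
  expect_true(mw$exact)
  expect_equal(mw$p_value, mw_enum_oracle(a, b))
  set.seed(11)
  for (i in 1:10) {
    x <- round(rnorm(sample(3:6, 1), 0, 10), 3)
    y <- round(rnorm(sample(3:6, 1), 1, 10), 3)
    if (any(duplicated(c(x, y)))) next
    expect_equal(mann_whitney(x, y)$p_value, mw_enum_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U is complementary and identical groups give p near 1", {
  set.seed(12)
  a <- rnorm(7); b <- rnorm(9)
  expect_equal(mann_whitney(a, b)$U + mann_whitney(b, a)$U, 63)
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_false(same$exact)  # ties force the approximate path
  expect_gte(same$p_value, 0.99)
  expect_error(mann_whitney(numeric(0), 1:3), class = "ocor_domain_error")
})

test_that("statistics are invariant to subject ordering", {
  set.seed(13)
  y <- matrix(rnorm(18, 650, 25), nrow = 6, ncol = 3)
  res <- results_from_matrix(y, times = c(7, 12, 20))
  perm <- res[sample(nrow(res)), ]
  expect_equal(paired_contrast(res, 7, 20), paired_contrast(perm, 7, 20))
  expect_equal(repeated_measures_anova(res, c(7, 12, 20)),
               repeated_measures_anova(perm, c(7, 12, 20)))
})
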