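test_that("3-month to monthly conversion: bounds and closed form", {
  expect_equal(three_month_to_monthly_prob(0), 0)
  expect_equal(three_month_to_monthly_prob(1), 1)
  expect_equal(three_month_to_monthly_prob(0.143), 1 - 0.857^(1 / 3))
  expect_equal(round(three_month_to_monthly_prob(0.143), 4), 0.0501)
  expect_error(three_month_to_monthly_prob(1.2),
               class = "oab_input_error")
})

test_that("monthly conversion composed over 3 cycles reproduces p3m", {
  for (p3m in c(0.01, 0.072, 0.143, 0.371, 0.9)) {
    pm <- three_month_to_monthly_prob(p3m)
    expect_equal(1 - (1 - pm)^3, p3m, tolerance = 1e-12)
  }
})

test_that("odds-ratio adjustment: identity, limits and arithmetic", {
  expect_equal(adjust_probability_by_odds_ratio(0.143, 1), 0.143)
  expect_equal(adjust_probability_by_odds_ratio(0.3, 1e-12), 0,
               tolerance = 1e-9)
  o <- 0.143 / 0.857
  expect_equal(adjust_probability_by_odds_ratio(0.143, 1.5),
               1.5 * o / (1 + 1.5 * o))
  expect_equal(round(adjust_probability_by_odds_ratio(0.143, 1.5), 4),
               0.2002)
  expect_error(adjust_probability_by_odds_ratio(1, 2),
               class = "oab_input_error")
  expect_error(adjust_probability_by_odds_ratio(0.5, 0),
               class = "oab_input_error")
})

test_that("odds-ratio adjustment is strictly increasing in OR and p_ref", {
  ors <- c(0.2, 0.5, 1, 2, 5)
  expect_true(all(diff(adjust_probability_by_odds_ratio(0.143, ors)) > 0))
  ps <- c(0.01, 0.1, 0.3, 0.6, 0.9)
  expect_true(all(diff(adjust_probability_by_odds_ratio(ps, 1.5)) > 0))
})

test_that("severity midpoints look up and validate", {
  mid <- list(micturition = c(6, 9, 11, 13, 16),
              incontinence = c(0, 0.5, 1.5, 3, 6))
  expect_equal(severity_to_daily_count(1, "micturition", mid), 6)
  expect_equal(severity_to_daily_count(1, "incontinence", mid), 0)
  custom <- list(micturition = c(5, 8, 10, 12, 20),
                 incontinence = c(0, 1, 2, 4, 8))
  expect_equal(severity_to_daily_count(5, "micturition", custom), 20)
  expect_error(severity_to_daily_count(6, "micturition", mid),
               class = "oab_input_error")
})

test_that("saturated transition fit equals observed frequencies", {
  # hand-built records: 4 patients, month 0 -> 1 transitions from level 1:
  # 1->1 three times, 1->2 once; from level 2: 2->1 once
  recs <- data.frame(
    patient_id = rep(1:5, each = 2),
    month = rep(0:1, 5),
    mict_level = c(1, 1, 1, 1, 1, 2, 1, 1, 2, 1),
    incont_level = 1
  )
  # months 2 and 3 absent: pad with constant level so all months exist
  recs23 <- do.call(rbind, lapply(2:3, function(m) {
    r <- recs[recs$month == 1, ]
    r$month <- m
    r
  }))
  recs <- rbind(recs, recs23)
  mats <- fit_transition_regression(recs, "micturition", n_levels = 3)
  expect_equal(mats$month1[1, ], c(0.75, 0.25, 0))
  expect_equal(mats$month1[2, ], c(1, 0, 0))
  # origin 3 never observed: identity row, flagged
  expect_equal(mats$month1[3, ], c(0, 0, 1))
  flagged <- attr(mats, "flagged")
  expect_true(any(vapply(flagged, function(x)
    x["month"] == 1 && x["origin"] == 3, logical(1))))
  # months 2-3 were constant: identity for observed origins
  expect_equal(mats$month2[1, 1], 1)
})

test_that("patients repeating their level yield identity matrices", {
  recs <- data.frame(
    patient_id = rep(1:10, each = 4),
    month = rep(0:3, 10),
    mict_level = rep(rep(1:5, 2), each = 4),
    incont_level = rep(rep(5:1, 2), each = 4)
  )
  for (dim in c("micturition", "incontinence")) {
    mats <- fit_transition_regression(recs, dim)
    for (m in 1:3) expect_equal(mats[[paste0("month", m)]], diag(5))
  }
})

test_that("transition fit recovers the generating matrices within 3 SE", {
  truth <- synthetic_truth(seed = 4)
  recs <- generate_trial_data(truth, 2000, seed = 4)
  for (dim in c("micturition", "incontinence")) {
    mats <- fit_transition_regression(recs, dim)
    col <- if (dim == "micturition") "mict_level" else "incont_level"
    for (m in 1:3) {
      M_true <- truth$transition[[dim]][[m]]
      M_fit <- mats[[paste0("month", m)]]
      expect_true(is_row_stochastic(M_fit))
      origins <- recs[recs$month == m - 1, col]
      for (i in 1:5) {
        n_i <- sum(origins == i)
        if (n_i < 30) next
        for (j in 1:5) {
          se <- sqrt(M_true[i, j] * (1 - M_true[i, j]) / n_i)
          expect_lte(abs(M_fit[i, j] - M_true[i, j]), 3 * se + 1e-12)
        }
      }
    }
  }
})

test_that("smoothed multinomial logit gives valid matrices", {
  truth <- synthetic_truth(seed = 4)
  recs <- generate_trial_data(truth, 500, seed = 4)
  mats <- fit_transition_regression(recs, "micturition",
                                    method = "smoothed")
  for (m in 1:3) {
    expect_true(is_row_stochastic(mats[[paste0("month", m)]],
                                  tol = 1e-6))
  }
})

test_that("empty input to the transition fit errors", {
  expect_error(fit_transition_regression(
    data.frame(patient_id = integer(), month = integer(),
               mict_level = integer(), incont_level = integer()),
    "micturition"), class = "oab_input_error")
})

test_that("utility regression interpolates noiseless data exactly", {
  # single country: its effect is absorbed and the covariate dropped, so
  # the intercept is exactly the generating base utility
  truth <- synthetic_truth(
    seed = 6, noise_sd = 0,
    covariate_effects = list(sex = -0.013, age = -0.0006,
                             country = c(uk = 0)))
  recs <- generate_trial_data(truth, 500, seed = 6)
  recs$age <- recs$age - 55  # generator centers age at 55
  fit <- fit_utility_regression(recs)
  expect_equal(fit$utility$base_utility, truth$utility$base,
               tolerance = 1e-8)
  expect_equal(fit$utility$mict_coefs, truth$utility$mict_coefs,
               tolerance = 1e-8)
  expect_equal(fit$utility$incont_coefs, truth$utility$incont_coefs,
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["sex"]), -0.013,
               tolerance = 1e-8)
})

test_that("utility regression recovers truth within 3 SE under noise", {
  truth <- synthetic_truth(seed = 7, noise_sd = 0.1)
  recs <- generate_trial_data(truth, 2000, seed = 7)
  recs$age <- recs$age - 55
  fit <- fit_utility_regression(recs)
  z_mict <- abs(fit$utility$mict_coefs - truth$utility$mict_coefs) /
    fit$se[paste0("mict_f", 1:4)]
  z_incont <- abs(fit$utility$incont_coefs - truth$utility$incont_coefs) /
    fit$se[paste0("incont_f", 1:4)]
  expect_true(all(z_mict < 3))
  expect_true(all(z_incont < 3))
})

test_that("rank-deficient utility design errors with the collinear terms", {
  recs <- data.frame(
    patient_id = 1:50, month = 0,
    mict_level = 5, incont_level = 5,
    eq5d_index = rnorm(50, 0.7, 0.05)
  )
  err <- expect_error(fit_utility_regression(recs),
                      class = "oab_estimation_error")
  expect_match(conditionMessage(err), "collinear")
})

test_that("predicted mean change: identity, hand case, linearity", {
  mid <- list(micturition = c(6, 9, 11, 13, 16),
              incontinence = c(0, 0.5, 1.5, 3, 6))
  idm <- lapply(1:3, function(m) diag(5))
  b <- c(0.3, 0.3, 0.2, 0.1, 0.1)
  expect_equal(predicted_mean_change(idm, b, "micturition", mid), 0)

  # all mass at level 2, matrices move everything to level 1
  to1 <- lapply(1:3, function(m) {
    M <- matrix(0, 5, 5); M[, 1] <- 1; M
  })
  b2 <- c(0, 1, 0, 0, 0)
  expect_equal(predicted_mean_change(to1, b2, "micturition", mid),
               6 - 9)

  # linearity in the baseline mixture
  mats <- synthetic_truth(seed = 1)$transition$micturition
  b_a <- c(1, 0, 0, 0, 0); b_b <- c(0, 0, 0, 0, 1)
  mix <- 0.3 * b_a + 0.7 * b_b
  expect_equal(
    predicted_mean_change(mats, mix, "micturition", mid),
    0.3 * predicted_mean_change(mats, b_a, "micturition", mid) +
      0.7 * predicted_mean_change(mats, b_b, "micturition", mid),
    tolerance = 1e-12)
})

test_that("latent shift is monotone and keeps matrices row-stochastic", {
  M <- synthetic_truth(seed = 1)$transition$micturition[[1]]
  expect_equal(shift_transition_matrix(M, 0), M)
  mid <- list(micturition = c(6, 9, 11, 13, 16),
              incontinence = c(0, 0.5, 1.5, 3, 6))
  b <- rowSums(baseline_from_decay())
  deltas <- seq(-2, 2, by = 0.5)
  changes <- vapply(deltas, function(d) {
    Ms <- lapply(1:3, function(m) shift_transition_matrix(M, d))
    expect_true(is_row_stochastic(Ms[[1]]))
    predicted_mean_change(Ms, b, "micturition", mid)
  }, numeric(1))
  # positive shift moves mass to better (lower-count) levels
  expect_true(all(diff(changes) < 0))
})

test_that("calibration: self-target, round trip and monotone sweep", {
  truth <- synthetic_truth(seed = 1)
  ref <- truth$transition$micturition
  B <- baseline_from_decay()
  mid <- list(micturition = c(6, 9, 11, 13, 16),
              incontinence = c(0, 0.5, 1.5, 3, 6))

  cal0 <- calibrate_comparator_transitions(ref, 0, B, "micturition", mid)
  expect_lt(abs(cal0$result$delta), 1e-5)
  expect_lt(cal0$result$objective_value, 1e-10)

  delta_star <- 0.4
  shifted <- lapply(ref, shift_transition_matrix, delta = delta_star)
  td <- predicted_mean_change(shifted, B, "micturition", mid) -
    predicted_mean_change(ref, B, "micturition", mid)
  cal <- calibrate_comparator_transitions(ref, td, B, "micturition", mid)
  expect_lt(abs(cal$result$delta - delta_star), 1e-3)

  targets <- seq(-1, 1, by = 0.25)
  achieved <- vapply(targets, function(td)
    calibrate_comparator_transitions(ref, td, B, "micturition",
                                     mid)$result$achieved_change,
    numeric(1))
  expect_true(all(diff(achieved) > 0))
  for (td in targets) {
    cal <- calibrate_comparator_transitions(ref, td, B, "micturition",
                                            mid)
    for (M in cal$mats) expect_true(is_row_stochastic(M))
  }
})

test_that("an unreachable calibration target warns with achieved value", {
  ref <- lapply(1:3, function(m) diag(5))  # identity cannot move counts
  B <- baseline_from_decay()
  mid <- list(micturition = c(6, 9, 11, 13, 16),
              incontinence = c(0, 0.5, 1.5, 3, 6))
  expect_warning(
    calibrate_comparator_transitions(ref, 3, B, "micturition", mid),
    class = "oab_calibration_warning")
})

test_that("transition matrix CSV round trip", {
  M <- synthetic_truth(seed = 1)$transition$incontinence[[2]]
  f <- tempfile(fileext = ".csv")
  write_transition_matrix(M, f)
  expect_equal(read_transition_matrix(f), M, tolerance = 1e-9)
})
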