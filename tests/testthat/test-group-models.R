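test_that("outlier exclusion applies the 3 SD rule", {
  ex <- exclude_outliers(c(0, 0, 0, 100))
  # hand z-scores: mean 25, sd 50 -> |z| = 1.5 for 100? no: (100-25)/50 = 1.5
  # with n-1 sd = 50: excluded only under a tighter rule; verify against a
  # direct computation instead of assuming
  z <- abs(c(0, 0, 0, 100) - 25) / sd(c(0, 0, 0, 100))
  expect_equal(ex$excluded, which(z > 3))
  big <- c(rnorm(100), 50)
  expect_equal(exclude_outliers(big)$excluded, 101L)
  same <- exclude_outliers(rep(3, 10))
  expect_equal(same$n_excluded, 0)
  # normal-tail oracle: ~0.27% excluded for a standard normal sample
  withr::with_seed(81, {
    frac <- exclude_outliers(rnorm(1e4))$n_excluded / 1e4
    expect_lt(abs(frac - 0.0027), 0.002)
  })
})

test_that("frequentist age model recovers a planted slope with honest intervals", {
  co <- generate_cohort(seed = 82)
  d <- simulate_measure_table(co, slope = -0.05, sd_between = 0.3,
                              sd_within = 0.3, seed = 82)
  fit <- fit_age_model(d, "outcome", age_model_spec(random_slopes = FALSE))
  age_row <- fit[fit$term == "age", ]
  expect_lt(age_row$lower, -0.05 + 0.03)
  expect_gt(age_row$upper, -0.05 - 0.03)
  expect_true(age_row$excludes_zero)
  # excludes_zero consistent with the interval on every row
  expect_equal(fit$excludes_zero, fit$lower > 0 | fit$upper < 0)
  expect_equal(age_row$n_scans, 183)
  expect_equal(age_row$n_participants, 98)
})

test_that("balanced noiseless linear data reduce to the OLS slope", {
  co <- tiny_cohort(0, 0, 20, seed = 83)
  d <- simulate_measure_table(co, slope = -0.04, sd_between = 0,
                              sd_within = 1e-8, fd_beta = 0, seed = 83)
  fit <- fit_age_model(d, "outcome",
                       age_model_spec(random_slopes = FALSE))
  ols <- coef(lm(outcome ~ I(age_at_scan - 12) + mean_fd, data = d))[2]
  expect_equal(fit$estimate[fit$term == "age"], unname(ols), tolerance = 1e-6)
  expect_equal(fit$estimate[fit$term == "age"], -0.04, tolerance = 1e-6)
})

test_that("zero-slope data excludes zero at roughly the nominal rate", {
  hits <- vapply(1:60, function(i) {
    co <- generate_cohort(cohort_config(n_by_scan_count = c(`1` = 30, `2` = 20,
                                                            `3` = 15)),
                          seed = 100 + i)
    d <- simulate_measure_table(co, slope = 0, sd_between = 0.3,
                                sd_within = 0.3, seed = 200 + i)
    fit <- fit_age_model(d, "outcome", age_model_spec(random_slopes = FALSE))
    fit$excludes_zero[fit$term == "age"]
  }, logical(1))
  # binomial(60, 0.05): observing more than 9 false positives has p < 1e-4
  expect_lte(sum(hits), 9)
})

test_that("row order does not change the frequentist estimate", {
  co <- tiny_cohort(6, 5, 5, seed = 84)
  d <- simulate_measure_table(co, slope = -0.05, seed = 84)
  f1 <- fit_age_model(d, "outcome", age_model_spec(random_slopes = FALSE))
  f2 <- fit_age_model(d[sample(nrow(d)), ], "outcome",
                      age_model_spec(random_slopes = FALSE))
  expect_equal(f1$estimate[f1$term == "age"], f2$estimate[f2$term == "age"],
               tolerance = 1e-8)
})

test_that("within/between decomposition flags cross-sectional data and recovers slopes", {
  cross <- generate_cohort(cohort_config(n_by_scan_count = c(`1` = 30)),
                           seed = 85)
  dc <- simulate_measure_table(cross, slope = -0.05, seed = 85)
  wb <- fit_within_between(dc, "outcome")
  expect_false(wb$converged[1])
  expect_true(is.na(wb$estimate[wb$term == "age_within"][1]))

  co <- generate_cohort(seed = 86)
  # equal within and between slopes
  d1 <- simulate_measure_table(co, slope = -0.05, sd_between = 0.2,
                               sd_within = 0.2, seed = 86)
  wb1 <- fit_within_between(d1, "outcome",
                            age_model_spec(random_slopes = FALSE))
  expect_lt(abs(wb1$estimate[wb1$term == "age_between"] + 0.05), 0.03)
  expect_lt(abs(wb1$estimate[wb1$term == "age_within"] + 0.05), 0.06)
  diff_row <- wb1[wb1$term == "within_minus_between", ]
  expect_true(diff_row$lower <= 0 & diff_row$upper >= 0)

  # between-only effect: between interval excludes 0, within covers 0
  hits <- vapply(1:20, function(i) {
    d2 <- simulate_measure_table(co, slope = -0.1, slope_within = 0,
                                 sd_between = 0.2, sd_within = 0.2,
                                 seed = 300 + i)
    wb2 <- fit_within_between(d2, "outcome",
                              age_model_spec(random_slopes = FALSE))
    b <- wb2[wb2$term == "age_between", ]
    w <- wb2[wb2$term == "age_within", ]
    c(b$excludes_zero & b$estimate < 0, !w$excludes_zero)
  }, logical(2))
  expect_gte(sum(hits[1, ]), 16) # >= 80% detection of the between slope
  expect_gte(sum(hits[2, ]), 12) # within term mostly covers 0
})

test_that("Bayesian and frequentist paths agree on a well-behaved fit", {
  co <- generate_cohort(seed = 87)
  d <- simulate_measure_table(co, slope = -0.05, sd_between = 0.3,
                              sd_within = 0.3, seed = 87)
  ff <- fit_age_model(d, "outcome", age_model_spec(random_slopes = FALSE))
  fb <- fit_age_model(d, "outcome",
                      age_model_spec(random_slopes = FALSE,
                                     estimation = "bayes_mcmc"), seed = 87)
  expect_true(fb$converged[1])
  expect_lt(abs(ff$estimate[ff$term == "age"] -
                  fb$estimate[fb$term == "age"]), 0.01)
  expect_true(fb$excludes_zero[fb$term == "age"])
})

test_that("robust fits downweight gross outliers", {
  co <- generate_cohort(seed = 88)
  d <- simulate_measure_table(co, slope = -0.05, sd_between = 0.2,
                              sd_within = 0.2, seed = 88)
  # inject contamination below the 3 SD exclusion threshold
  idx <- order(d$age_at_scan)[1:12]
  d$outcome[idx] <- d$outcome[idx] + 2.2 * sd(d$outcome)
  plain <- fit_age_model(d, "outcome", age_model_spec(random_slopes = FALSE))
  rob <- fit_age_model(d, "outcome",
                       age_model_spec(random_slopes = FALSE,
                                      outlier_rule = "exclude_3sd_plus_robust"))
  err_plain <- abs(plain$estimate[plain$term == "age"] + 0.05)
  err_rob <- abs(rob$estimate[rob$term == "age"] + 0.05)
  expect_lt(err_rob, err_plain)
})

test_that("trial-dynamics models recover a habituation x age interaction", {
  d <- default_design()
  p <- quiet_params(participant_amp_sd = 0.1)
  hits <- vapply(1:20, function(i) {
    co <- generate_cohort(cohort_config(
      n_by_scan_count = c(`1` = 30, `2` = 20, `3` = 15)), seed = 400 + i)
    tt <- simulate_trial_table(co, d, p, meas_noise_sd = 0.3, seed = 500 + i)
    tt <- tt[tt$condition == "fear", ]
    tt$beta <- tt$beta_seed
    slopes <- dplyr::group_by(tt, .data$participant_id, .data$scan_id,
                              .data$age_at_scan, .data$mean_fd) |>
      dplyr::summarise(slope = trial_slope(.data$beta,
                                           .data$trial_index)$slope,
                       .groups = "drop")
    fit <- fit_trial_dynamics_models(slopes, "slopes_on_age",
                                     age_model_spec(random_slopes = FALSE))
    # steeper (more negative) slopes at younger ages: positive age effect
    fit$estimate[fit$term == "age"] > 0
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("halves and single-trial variants agree in interaction sign", {
  d <- default_design()
  p <- quiet_params(habituation_slope = -0.06, habituation_age_slope = 0.004,
                    participant_amp_sd = 0.1)
  agree <- vapply(1:10, function(i) {
    co <- generate_cohort(cohort_config(
      n_by_scan_count = c(`1` = 20, `2` = 15, `3` = 10)), seed = 600 + i)
    tt <- simulate_trial_table(co, d, p, meas_noise_sd = 0.2, seed = 700 + i)
    tt <- tt[tt$condition == "fear", ]
    tt$beta <- tt$beta_seed
    halves <- dplyr::group_by(tt, .data$participant_id, .data$scan_id,
                              .data$age_at_scan, .data$mean_fd) |>
      dplyr::reframe(half = c(1, 2),
                     half_mean = c(half_means(.data$beta,
                                              .data$trial_index)$first,
                                   half_means(.data$beta,
                                              .data$trial_index)$second))
    fh <- fit_trial_dynamics_models(halves, "halves_interaction",
                                    age_model_spec(random_slopes = FALSE))
    fs <- fit_trial_dynamics_models(tt, "single_trial",
                                    age_model_spec(random_slopes = FALSE))
    fh$estimate[fh$term == "age:half"] > 0 &&
      fs$estimate[fs$term == "age:trial"] > 0
  }, logical(1))
  # habituation weakens with age, so both the age x trial interaction and the
  # age effect on the (second - first) half difference are positive
  expect_gte(sum(agree), 9)
})

test_that("kNN imputation matches a brute-force oracle", {
  co <- generate_cohort(cohort_config(n_by_scan_count = c(`1` = 30)), seed = 89)
  anx <- generate_anxiety_scores(co, generative_params(), seed = 89,
                                 missing_frac = 0)
  items <- anx$scared_items[!anx$scores$adult, ]
  expect_equal(impute_scared_items(items)[, -(1:2)], items[, -(1:2)],
               ignore_attr = TRUE)

  # k = 1 with an identical-other-items row
  m <- tibble::tibble(i1 = c(1, 1, 5), i2 = c(2, 2, 9), i3 = c(7, NA, 0))
  out <- impute_scared_items(m, k = 1)
  expect_equal(out$i3[2], 7)

  # brute-force neighbour search on random 20 x 8 tables
  withr::with_seed(90, {
    for (rep in 1:5) {
      M <- matrix(rnorm(160), 20, 8)
      M[sample(160, 12)] <- NA
      keep <- rowSums(!is.na(M)) > 0
      M <- M[keep, , drop = FALSE]
      tab <- tibble::as_tibble(as.data.frame(M))
      out <- impute_scared_items(tab, k = 5)
      mu <- colMeans(M, na.rm = TRUE); s <- apply(M, 2, sd, na.rm = TRUE)
      Z <- sweep(sweep(M, 2, mu), 2, s, "/")
      for (i in seq_len(nrow(M))) {
        for (j in which(is.na(M[i, ]))) {
          cand <- which(!is.na(M[, j]) & seq_len(nrow(M)) != i)
          dd <- sapply(cand, function(r) {
            sh <- !is.na(Z[i, ]) & !is.na(Z[r, ])
            if (!any(sh)) return(Inf)
            sqrt(mean((Z[i, sh] - Z[r, sh])^2))
          })
          cand <- cand[is.finite(dd)]; dd <- dd[is.finite(dd)]
          use <- cand[order(dd, cand)][seq_len(min(5, length(cand)))]
          expect_equal(out[[j]][i], mean(M[use, j]), tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("anxiety association coefficients are invariant to affine rescaling", {
  co <- generate_cohort(seed = 91)
  d <- simulate_measure_table(co, slope = -0.03, seed = 91)
  withr::with_seed(91, {
    d$anx_raw <- 5 + 0.3 * d$outcome + rnorm(nrow(d), 0, 1)
  })
  d$anx_scaled <- 7 + 13 * d$anx_raw
  f1 <- fit_brain_anxiety_model(d, "outcome", "anx_raw",
                                age_model_spec(random_slopes = FALSE))
  f2 <- fit_brain_anxiety_model(d, "outcome", "anx_scaled",
                                age_model_spec(random_slopes = FALSE))
  expect_equal(f1$estimate[f1$term == "brain"],
               f2$estimate[f2$term == "brain"], tolerance = 1e-8)
  expect_gt(f1$estimate[f1$term == "brain"], 0)
})

test_that("a planted brain-anxiety coefficient is detected and nulls stay null", {
  hits_alt <- 0; hits_null <- 0
  for (i in 1:20) {
    co <- generate_cohort(cohort_config(
      n_by_scan_count = c(`1` = 30, `2` = 20, `3` = 15)), seed = 800 + i)
    d <- simulate_measure_table(co, slope = 0, seed = 800 + i)
    withr::with_seed(900 + i, {
      d$anx_alt <- 0.3 * scale(d$outcome)[, 1] + rnorm(nrow(d))
      d$anx_null <- rnorm(nrow(d))
    })
    fa <- fit_brain_anxiety_model(d, "outcome", "anx_alt",
                                  age_model_spec(random_slopes = FALSE))
    fn <- fit_brain_anxiety_model(d, "outcome", "anx_null",
                                  age_model_spec(random_slopes = FALSE))
    hits_alt <- hits_alt +
      (fa$excludes_zero[fa$term == "brain"] &&
         fa$estimate[fa$term == "brain"] > 0)
    hits_null <- hits_null + fn$excludes_zero[fn$term == "brain"]
  }
  expect_gte(hits_alt, 18)
  expect_lte(hits_null, 4) # binomial(20, .05): > 4 has p < 0.003
})
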