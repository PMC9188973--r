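test_that("deconvolution is linear, shrinks with lambda, and round-trips", {
  h <- make_hrf("double_gamma")
  n <- 130
  expect_equal(deconvolve(rep(0, n), h, 2), rep(0, n))
  # round-trip oracle: noiseless y = conv(H, n0), tiny lambda
  set.seed(61)
  n0 <- rnorm(n)
  H <- specfmri:::hrf_volume_matrix(h, 2, n)
  y <- drop(H %*% n0)
  n_hat <- deconvolve(y, h, 2, ridge_lambda = 1e-8)
  expect_lt(sqrt(sum((drop(H %*% n_hat) - y)^2) / sum(y^2)), 1e-3)
  # heavy ridge shrinks the output toward zero
  big <- deconvolve(y, h, 2, ridge_lambda = 1e6)
  expect_lt(sqrt(sum(big^2)), 1e-3 * sqrt(sum(n_hat^2)))
  expect_error(deconvolve(c(1, NA, 3), h, 2), "finite")
})

test_that("gPPI design construction follows the product/deconvolution recipes", {
  d <- default_design()
  nv <- d$n_volumes
  set.seed(62)
  seed_ts <- rnorm(nv)
  g <- build_gppi_design(seed_ts, d, deconvolve = FALSE)
  expect_equal(sort(g$ppi_cols), c("ppi_fear", "ppi_neutral"))
  expect_equal(sum(colnames(g$X) == "physio"), 1)
  # elementwise product oracle (uncentered, no deconvolution)
  physio <- seed_ts - mean(seed_ts)
  expect_equal(unname(g$X[, "ppi_fear"]),
               physio * g$X[, "psych_fear"], tolerance = 1e-12)
  # task centering changes the ppi column but not the psych columns
  gc <- build_gppi_design(seed_ts, d, deconvolve = FALSE, center_task = TRUE)
  expect_equal(gc$X[, "psych_fear"], g$X[, "psych_fear"])
  expect_false(isTRUE(all.equal(gc$X[, "ppi_fear"], g$X[, "ppi_fear"])))
  # zero seed is degenerate
  expect_error(build_gppi_design(rep(0, nv), d), "constant")
  # deconvolution and product forks produce different ppi regressors
  gd <- build_gppi_design(seed_ts, d, deconvolve = TRUE)
  expect_gt(max(abs(gd$X[, "ppi_fear"] - g$X[, "ppi_fear"])), 1e-3)
})

test_that("non-deconvolution gPPI betas scale as 1/c when the seed is scaled by c", {
  d <- default_design()
  nv <- d$n_volumes
  set.seed(63)
  seed_ts <- rnorm(nv) + 0.3 * sin(seq_len(nv) / 9)
  target <- rnorm(nv)
  g1 <- build_gppi_design(seed_ts, d, deconvolve = FALSE)
  g2 <- build_gppi_design(3 * seed_ts, d, deconvolve = FALSE)
  f1 <- fit_gppi(target, g1, prewhiten = "none")
  f2 <- fit_gppi(target, g2, prewhiten = "none")
  ppi1 <- f1$estimate[f1$term == "ppi fear>baseline"]
  ppi2 <- f2$estimate[f2$term == "ppi fear>baseline"]
  expect_equal(ppi2, ppi1 / 3, tolerance = 1e-8)
})

test_that("a target equal to the seed gives physio beta 1 and null ppi betas", {
  d <- default_design()
  nv <- d$n_volumes
  set.seed(64)
  seed_ts <- as.numeric(stats::filter(rnorm(nv), 0.4, method = "recursive"))
  g <- build_gppi_design(seed_ts, d, deconvolve = FALSE)
  f <- fit_gppi(seed_ts, g, prewhiten = "none")
  expect_equal(f$estimate[f$term == "physio"], 1, tolerance = 1e-8)
  expect_lt(max(abs(f$estimate[startsWith(f$term, "ppi")])), 1e-8)
})

test_that("condition-dependent amplitude coupling yields positive fear>neutral gPPI", {
  d <- default_design()
  co <- generate_cohort(cohort_config(n_by_scan_count = c(`1` = 60)), seed = 65)
  p <- quiet_params(coupling_rho = c(fear = 0.8, neutral = 0.0),
                    noise_sd = 0.4, trial_amp_sd = 0.8,
                    habituation_slope = 0, habituation_age_slope = 0,
                    age_slope = c(fear = 0, neutral = 0),
                    participant_amp_sd = 0)
  scans <- simulate_cohort_scans(co, d, p, seed = 66)
  est <- compute_gppi_estimates(scans, deconv_options = FALSE,
                                targets = "mpfc1")
  fn <- est$estimate[est$term == "ppi fear>neutral"]
  expect_gt(mean(fn) / (sd(fn) / sqrt(length(fn))), 2)
  expect_gt(mean(fn), 0)
})

test_that("zero coupling leaves the ppi beta distribution centered at zero", {
  d <- default_design()
  co <- generate_cohort(cohort_config(n_by_scan_count = c(`1` = 80)), seed = 67)
  p <- quiet_params(coupling_rho = c(fear = 0, neutral = 0),
                    noise_sd = 0.4, trial_amp_sd = 0.8,
                    age_slope = c(fear = 0, neutral = 0),
                    habituation_slope = 0, habituation_age_slope = 0,
                    participant_amp_sd = 0)
  scans <- simulate_cohort_scans(co, d, p, seed = 68)
  est <- compute_gppi_estimates(scans, deconv_options = FALSE,
                                targets = "mpfc1")
  fb <- est$estimate[est$term == "ppi fear>baseline"]
  expect_lt(abs(mean(fb)), 2 * sd(fb) / sqrt(length(fb)) + 0.02)
})

test_that("beta-series correlation handles perfect, null and degenerate input", {
  set.seed(69)
  a <- rnorm(24)
  perfect <- bsc(a, a + 5)
  expect_true(perfect$clamped)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$z, atanh(1 - 1e-6))
  expect_true(is.na(bsc(rep(1, 24), a)$z))
  expect_match(bsc(rep(1, 24), a)$missing_reason, "zero-variance")
  expect_true(is.na(bsc(a[1:3], a[1:3])$z))
  # symmetry on random tables
  for (i in 1:20) {
    x <- rnorm(24); y <- rnorm(24)
    expect_equal(bsc(x, y)$z, bsc(y, x)$z)
  }
  # null simulation: mean z within 2 MC-SE of 0 over 1000 reps
  zs <- vapply(1:1000, function(i) bsc(rnorm(24), rnorm(24))$z, numeric(1))
  expect_lt(abs(mean(zs)), 2 * sd(zs) / sqrt(length(zs)) + 0.01)
  # Fisher z strictly increasing in r
  rs <- seq(-0.9, 0.9, by = 0.1)
  expect_true(all(diff(atanh(rs)) > 0))
})

test_that("BSC is invariant to common per-trial offsets after centering", {
  set.seed(70)
  base <- tibble::tibble(
    scan_id = "s", condition = "fear", trial_index = 1:24,
    gss_applied = FALSE)
  long <- dplyr::bind_rows(
    dplyr::mutate(base, roi = "a", beta = rnorm(24)),
    dplyr::mutate(base, roi = "b", beta = rnorm(24)))
  offset <- rep(rnorm(24), 2)
  long_off <- dplyr::mutate(long, beta = beta + offset)
  c1 <- apply_global_signal_centering(long)
  c2 <- apply_global_signal_centering(long_off)
  z1 <- bsc(c1$beta[c1$roi == "a"], c1$beta[c1$roi == "b"])$z
  z2 <- bsc(c2$beta[c2$roi == "a"], c2$beta[c2$roi == "b"])$z
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("method concordance matches a brute-force Spearman oracle", {
  set.seed(71)
  n <- 30
  tab <- dplyr::bind_rows(
    tibble::tibble(scan_id = sprintf("s%d", 1:n), fork = "m1",
                   estimate = rnorm(n)),
    tibble::tibble(scan_id = sprintf("s%d", 1:n), fork = "m2",
                   estimate = rnorm(n)),
    tibble::tibble(scan_id = sprintf("s%d", 1:n), fork = "m3",
                   estimate = rnorm(n)))
  cm <- fc_method_concordance(tab)
  expect_equal(dim(cm), c(3, 3))
  expect_equal(unname(diag(cm)), rep(1, 3))
  m1 <- tab$estimate[tab$fork == "m1"]
  m2 <- tab$estimate[tab$fork == "m2"]
  oracle <- cor(rank(m1), rank(m2))
  expect_equal(unname(cm["m1", "m2"]), oracle, tolerance = 1e-12)
  # independent vectors: near-zero off-diagonals
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.5)
  # duplicated fork columns correlate perfectly
  tab2 <- dplyr::bind_rows(tab, dplyr::mutate(
    tab[tab$fork == "m1", ], fork = "m1_copy"))
  cm2 <- fc_method_concordance(tab2)
  expect_equal(unname(cm2["m1", "m1_copy"]), 1)
})
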