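# HRF convolution matrix on the volume grid: lower-triangular Toeplitz of the
# kernel sampled at multiples of TR.
hrf_volume_matrix <- function(hrf, tr, n_volumes) {
  h <- hrf$values[seq(1, length(hrf$values), by = round(tr / hrf$dt))]
  h <- h[seq_len(min(length(h), n_volumes))]
  H <- matrix(0, n_volumes, n_volumes)
  for (k in seq_along(h)) {
    idx <- seq_len(n_volumes - k + 1)
    H[cbind(idx + k - 1, idx)] <- h[k]
  }
  H * tr
}

#' Ridge deconvolution of a BOLD series to the neural scale
#'
#' Solves `argmin ||H n - y||^2 + lambda ||n||^2` on the volume grid, where
#' `H` is the HRF convolution operator. `ridge_lambda` is expressed relative
#' to the mean diagonal of `H'H`, so its effect is invariant to signal and
#' kernel scaling. With `lambda -> 0` the round trip `H n` reproduces a
#' noiseless convolved input; with large `lambda` the output shrinks to zero.
#'
#' @param bold_ts numeric series on the volume grid.
#' @param hrf HRF kernel.
#' @param tr repetition time, seconds.
#' @param ridge_lambda relative ridge penalty (default 1).
#' @return Numeric neural-scale series of the same length.
#' @export
deconvolve <- function(bold_ts, hrf = make_hrf("double_gamma"), tr = 2,
                       ridge_lambda = 1) {
  assert_that(all(is.finite(bold_ts)), "BOLD series must be finite")
  assert_that(ridge_lambda >= 0, "ridge_lambda must be >= 0")
  n <- length(bold_ts)
  H <- hrf_volume_matrix(hrf, tr, n)
  HtH <- crossprod(H)
  lam <- ridge_lambda * mean(diag(HtH))
  drop(solve(HtH + diag(lam, n), crossprod(H, bold_ts)))
}

# task indicator on the volume grid: fine-grid boxcars (350 ms events on a
# 0.1 s grid) bin-averaged into TR bins
task_indicator_volumes <- function(onsets, durations, tr, n_volumes, dt = 0.1) {
  n_fine <- round(tr / dt) * n_volumes
  tgrid <- (seq_len(n_fine) - 1) * dt
  stim <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    idx <- which(tgrid >= onsets[i] & tgrid < onsets[i] + durations[i])
    if (length(idx) == 0) idx <- max(1L, min(n_fine, 1L + round(onsets[i] / dt)))
    stim[idx] <- 1
  }
  downsample_to_volumes(stim, dt, tr, n_volumes)
}

#' Build a generalized PPI design
#'
#' One interaction (PPI) regressor per condition plus the physiological
#' (seed) term and the convolved task (psych) regressors. With
#' `deconvolve = TRUE` the interaction is formed at the neural scale — the
#' seed is ridge-deconvolved, multiplied by the (optionally centered) task
#' indicator, and re-convolved with the HRF. Without deconvolution the
#' interaction is the elementwise product of the mean-removed seed and the
#' (optionally centered) convolved task regressor.
#'
#' @param seed_ts seed ROI timeseries (volume grid).
#' @param design task design.
#' @param hrf HRF kernel.
#' @param deconvolve logical, apply the deconvolution step.
#' @param center_task center the task regressor before forming the
#'   interaction.
#' @param rp,fd_series,nuisance_set,detrend nuisance specification as in
#'   [build_design_matrix()].
#' @param ridge_lambda penalty for the deconvolution step.
#' @return A `gppi_design`: list with `X`, `weights`, `ppi_cols`,
#'   `deconvolved`, `task_centered`.
#' @export
build_gppi_design <- function(seed_ts, design, hrf = make_hrf("double_gamma"),
                              deconvolve = FALSE, center_task = FALSE,
                              rp = NULL, fd_series = NULL,
                              nuisance_set = "24", detrend = "highpass",
                              ridge_lambda = 1) {
  assert_that(sd(seed_ts) > 0, "seed timeseries is constant (degenerate physio)")
  e <- design$events
  nv <- design$n_volumes
  conds <- sort(unique(e$trial_type))
  physio <- seed_ts - mean(seed_ts)
  psych <- vapply(conds, function(cc) {
    sel <- e$trial_type == cc
    convolve_events(e$onset[sel], e$duration[sel], hrf, design$tr, nv)
  }, numeric(nv))
  colnames(psych) <- paste0("psych_", conds)

  if (deconvolve) {
    neural <- specfmri::deconvolve(physio, hrf, design$tr, ridge_lambda)
    ppi <- vapply(conds, function(cc) {
      sel <- e$trial_type == cc
      ind <- task_indicator_volumes(e$onset[sel], e$duration[sel], design$tr, nv)
      if (center_task) ind <- ind - mean(ind)
      H <- hrf_volume_matrix(hrf, design$tr, nv)
      drop(H %*% (neural * ind))
    }, numeric(nv))
  } else {
    ppi <- vapply(conds, function(cc) {
      tk <- psych[, paste0("psych_", cc)]
      if (center_task) tk <- tk - mean(tk)
      physio * tk
    }, numeric(nv))
  }
  colnames(ppi) <- paste0("ppi_", conds)

  X <- cbind(psych, physio = physio, ppi)
  weights <- rep(1, nv)
  if (!is.null(rp)) {
    X <- cbind(X, expand_motion_regressors(rp, nuisance_set))
  }
  X <- cbind(X, detrend_basis(detrend, nv, design$tr))
  if (!is.null(fd_series)) weights <- censor_weights(fd_series)$weights
  structure(list(X = X, weights = weights,
                 ppi_cols = colnames(ppi), conds = conds,
                 deconvolved = deconvolve, task_centered = center_task),
            class = "gppi_design")
}

#' Fit a gPPI model for one target ROI
#'
#' GLM of the target timeseries on the full gPPI design; contrasts are taken
#' on the PPI betas (fear > baseline is the fear PPI beta, fear > neutral
#' their difference) and the physio beta is reported as task-independent
#' coupling.
#'
#' @param target_ts target ROI timeseries.
#' @param gppi a [build_gppi_design()] object.
#' @param prewhiten `"ar1"` or `"none"`.
#' @param collinearity_limit absolute correlation between a PPI column and any
#'   psych/physio column above which a warning flag is recorded.
#' @return Tibble with rows for each PPI contrast and the physio term:
#'   `term`, `estimate`, `se`, `t_stat`, `dof`, `deconvolved`,
#'   `task_centered`, `collinearity_flag`.
#' @export
fit_gppi <- function(target_ts, gppi, prewhiten = c("ar1", "none"),
                     collinearity_limit = 0.99) {
  prewhiten <- match.arg(prewhiten)
  fit <- wls_core(matrix(target_ts, ncol = 1), gppi$X, gppi$weights, prewhiten)
  base_cols <- c(paste0("psych_", gppi$conds), "physio")
  cc <- suppressWarnings(
    cor(gppi$X[, gppi$ppi_cols, drop = FALSE],
        gppi$X[, base_cols, drop = FALSE]))
  coll <- any(abs(cc) > collinearity_limit, na.rm = TRUE)

  term_est <- function(cv_names, cv_vals, label) {
    cv <- numeric(ncol(gppi$X)); names(cv) <- colnames(gppi$X)
    cv[cv_names] <- cv_vals
    est <- drop(crossprod(cv, fit$beta))
    se <- sqrt(max(0, drop(crossprod(cv, fit$XtXinv %*% cv)) * fit$sigma2))
    tibble::tibble(term = label, estimate = est, se = se,
                   t_stat = ifelse(se > 0, est / se, NA_real_), dof = fit$dof)
  }
  out <- dplyr::bind_rows(
    term_est("ppi_fear", 1, "ppi fear>baseline"),
    term_est("ppi_neutral", 1, "ppi neutral>baseline"),
    term_est(c("ppi_fear", "ppi_neutral"), c(1, -1), "ppi fear>neutral"),
    term_est("physio", 1, "physio")
  )
  out$deconvolved <- gppi$deconvolved
  out$task_centered <- gppi$task_centered
  out$collinearity_flag <- coll
  out
}

#' Beta-series correlation between two ROIs
#'
#' Pearson correlation across one condition's paired trial betas, Fisher
#' z-transformed. Perfect correlations are clamped to |r| = 1 - 1e-6 and
#' flagged; zero-variance series return `NA` with a degeneracy reason.
#'
#' @param seed_beta,target_beta paired per-trial betas (same condition/order).
#' @param min_pairs minimum number of complete pairs (default 4).
#' @return Tibble row: `r`, `z`, `n_pairs`, `clamped`, `missing_reason`.
#' @export
bsc <- function(seed_beta, target_beta, min_pairs = 4) {
  ok <- !is.na(seed_beta) & !is.na(target_beta)
  if (sum(ok) < min_pairs) {
    return(tibble::tibble(r = NA_real_, z = NA_real_, n_pairs = sum(ok),
                          clamped = FALSE,
                          missing_reason = "fewer pairs than required"))
  }
  a <- seed_beta[ok]; b <- target_beta[ok]
  if (sd(a) == 0 || sd(b) == 0) {
    return(tibble::tibble(r = NA_real_, z = NA_real_, n_pairs = sum(ok),
                          clamped = FALSE,
                          missing_reason = "zero-variance beta series"))
  }
  r <- cor(a, b)
  clamped <- abs(r) >= 1
  r_use <- max(-1 + 1e-6, min(1 - 1e-6, r))
  tibble::tibble(r = r, z = atanh(r_use), n_pairs = sum(ok), clamped = clamped,
                 missing_reason = NA_character_)
}

#' Rank-order concordance of scan-level FC estimates across methods/forks
#'
#' @param fc_table tibble with columns `scan_id`, `fork` (method x fork
#'   label) and `estimate`.
#' @return Spearman correlation matrix across forks (pairwise complete scans).
#' @export
fc_method_concordance <- function(fc_table) {
  wide <- tidyr::pivot_wider(fc_table[, c("scan_id", "fork", "estimate")],
                             names_from = "fork", values_from = "estimate")
  m <- as.matrix(wide[, -1, drop = FALSE])
  assert_that(nrow(m) >= 3, "need at least 3 scans for concordance")
  suppressWarnings(cor(m, method = "spearman", use = "pairwise.complete.obs"))
}
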