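#' Least-squares-separate (LSS) single-trial betas
#'
#' Fits one GLM per trial (48 for the default design): the target trial gets
#' its own regressor, the remaining trials are collapsed into a single
#' regressor, and every model carries the nuisance set, the drift basis and
#' the FD-censoring weights. A trial whose regressor falls entirely on
#' censored volumes is returned as `NA` with a reason.
#'
#' @param roi_ts vector/matrix/tibble of ROI timeseries (n_volumes rows).
#' @param design a [generate_task_design()] object.
#' @param rp realignment parameters.
#' @param fd_series per-volume FD.
#' @param hrf HRF kernel.
#' @param nuisance_set,detrend as in [build_design_matrix()].
#' @param wm,csf tissue signals for the `"18_wm_csf"` nuisance set.
#' @param scan_id label copied into the output.
#' @return Trial-beta tibble: one row per (roi, trial) with `condition`,
#'   `trial_index`, `beta`, `missing_reason`, `gss_applied = FALSE`.
#' @export
fit_lss <- function(roi_ts, design, rp, fd_series,
                    hrf = make_hrf("double_gamma"),
                    nuisance_set = "24", detrend = "highpass",
                    wm = NULL, csf = NULL, scan_id = "scan") {
  Y <- as.matrix(roi_ts)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("roi", seq_len(ncol(Y)))
  e <- design$events
  n_trials <- nrow(e)
  base <- cbind(
    detrend_basis(detrend, design$n_volumes, design$tr),
    expand_motion_regressors(rp, nuisance_set, wm = wm, csf = csf)
  )
  cw <- censor_weights(fd_series)
  trial_reg <- vapply(seq_len(n_trials), function(i)
    convolve_events(e$onset[i], e$duration[i], hrf, design$tr,
                    design$n_volumes), numeric(design$n_volumes))
  all_reg <- rowSums(trial_reg)

  rows <- lapply(seq_len(n_trials), function(i) {
    target <- trial_reg[, i]
    supported <- which(target > 0.05 * max(target))
    if (all(cw$weights[supported] == 0)) {
      return(tibble::tibble(scan_id = scan_id, roi = colnames(Y),
                            condition = e$trial_type[i],
                            trial_index = e$trial_index[i],
                            beta = NA_real_,
                            missing_reason = "trial fully censored"))
    }
    X <- cbind(target = target, others = all_reg - target, base)
    fit <- wls_core(Y, X, cw$weights, prewhiten = "none")
    tibble::tibble(scan_id = scan_id, roi = colnames(Y),
                   condition = e$trial_type[i],
                   trial_index = e$trial_index[i],
                   beta = as.numeric(fit$beta["target", ]),
                   missing_reason = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  out$gss_applied <- FALSE
  out
}

#' Post hoc distribution centering of trial betas across ROIs
#'
#' For every (scan, trial), subtracts the across-ROI mean beta from each ROI's
#' beta — a global-signal correction at the single-trial level. Pairwise
#' between-ROI differences are preserved exactly, and adding a common offset
#' to all ROIs of a trial leaves the centered values unchanged.
#'
#' @param beta_table long trial-beta tibble (as from [fit_lss()], possibly
#'   several scans) covering at least two ROIs.
#' @param rois ROI panel over which the per-trial mean is computed; defaults
#'   to all ROIs present.
#' @return The table with centered `beta` and `gss_applied = TRUE`.
#' @export
apply_global_signal_centering <- function(beta_table, rois = NULL) {
  rois <- rois %||% unique(beta_table$roi)
  assert_that(length(rois) >= 2,
              "global-signal centering needs at least two ROIs")
  sub <- beta_table$roi %in% rois
  key <- interaction(beta_table$scan_id, beta_table$condition,
                     beta_table$trial_index, drop = TRUE)
  trial_mean <- stats::ave(ifelse(sub, beta_table$beta, NA), key,
                           FUN = function(v) mean(v, na.rm = TRUE))
  out <- beta_table
  out$beta <- beta_table$beta - trial_mean
  out$gss_applied <- TRUE
  out
}

#' Rank-order (Spearman) slope of trial betas over trial number
#'
#' @param beta per-trial betas of one (scan, roi, condition), `NA` allowed.
#' @param trial_index matching within-condition trial numbers.
#' @return List: `slope` (Spearman rho; 0 with `degenerate = TRUE` for a
#'   constant series; `NA` with a `missing_reason` when < 3 usable trials),
#'   `n_used`, `degenerate`.
#' @export
trial_slope <- function(beta, trial_index) {
  ok <- !is.na(beta)
  if (sum(ok) < 3) {
    return(list(slope = NA_real_, n_used = sum(ok), degenerate = FALSE,
                missing_reason = "fewer than 3 usable trials"))
  }
  b <- beta[ok]; idx <- trial_index[ok]
  if (sd(b) == 0) {
    return(list(slope = 0, n_used = sum(ok), degenerate = TRUE,
                missing_reason = NA_character_))
  }
  list(slope = suppressWarnings(cor(b, idx, method = "spearman")),
       n_used = sum(ok), degenerate = FALSE, missing_reason = NA_character_)
}

#' First-half / second-half mean betas
#'
#' Means over within-condition trials 1-12 and 13-24, ignoring flagged-missing
#' betas; an empty half is returned as `NA`.
#'
#' @param beta,trial_index as in [trial_slope()] (24 trials expected).
#' @param split trial index at which the second half starts (default 13).
#' @return List: `first`, `second`, `n_first`, `n_second`.
#' @export
half_means <- function(beta, trial_index, split = 13) {
  first <- beta[trial_index < split & !is.na(beta)]
  second <- beta[trial_index >= split & !is.na(beta)]
  list(first = if (length(first)) mean(first) else NA_real_,
       second = if (length(second)) mean(second) else NA_real_,
       n_first = length(first), n_second = length(second))
}

#' Scan-level trial-dynamics summaries for a trial-beta table
#'
#' Applies [trial_slope()] and [half_means()] per (scan, roi, condition).
#'
#' @param beta_table long trial-beta tibble.
#' @return Tibble with `slope`, `slope_degenerate`, `first_half`,
#'   `second_half` per (scan_id, roi, condition).
#' @export
trial_dynamics_table <- function(beta_table) {
  dplyr::group_by(beta_table, .data$scan_id, .data$roi, .data$condition) |>
    dplyr::summarise(
      slope = trial_slope(.data$beta, .data$trial_index)$slope,
      slope_degenerate = trial_slope(.data$beta, .data$trial_index)$degenerate,
      first_half = half_means(.data$beta, .data$trial_index)$first,
      second_half = half_means(.data$beta, .data$trial_index)$second,
      .groups = "drop"
    )
}
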